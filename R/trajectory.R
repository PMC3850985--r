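# Acquisition geometry: modified golden-angle ordering, asymmetric radial
# sample positions, and the linear gradient-delay model.

#' Acquisition configuration
#'
#' Protocol parameters of the retrospectively gated radial phase-contrast
#' sequence. Defaults reproduce the retrospective protocol: TR 3 ms, 16000
#' projections per velocity encoding, 90 readout points with the gradient echo
#' at 10 % of the readout, 160 reconstruction matrix over a 24 mm field of
#' view, 75.8 kHz sampling bandwidth, first gradient moments
#' (expressed as gamma*M1/2pi) of 0 and +/-0.3 s/m, and a 15 s pause between
#' the three velocity-encoding steps.
#'
#' @param tr repetition time (s).
#' @param n_proj projections per velocity encoding.
#' @param n_readout samples per projection.
#' @param echo_fraction echo position as a fraction of the readout.
#' @param matrix reconstruction grid edge (pixels).
#' @param fov field of view (m).
#' @param sampling_bw readout bandwidth (Hz).
#' @param te echo time (s), time from excitation to the echo sample.
#' @param m1_values first gradient moments, gamma*M1/2pi in s/m.
#' @param wait_between_encodings pause between velocity encodings (s).
#' @return an object of class `acq_config`.
#' @export
acq_config <- function(tr = 3e-3, n_proj = 16000, n_readout = 90,
                       echo_fraction = 0.10, matrix = 160, fov = 24e-3,
                       sampling_bw = 75800, te = 1.2e-3,
                       m1_values = c(0, 0.3, -0.3),
                       wait_between_encodings = 15) {
  if (tr <= 0) abort_config("tr must be positive")
  if (n_proj < 1) abort_config("n_proj must be >= 1")
  if (matrix <= 0 || fov <= 0) abort_config("matrix and fov must be positive")
  idx_echo <- round(echo_fraction * n_readout)
  if (idx_echo < 0 || idx_echo >= n_readout)
    abort_config("echo position must lie within the readout")
  if (!any(m1_values == 0) ||
      !any(m1_values > 0 & vapply(m1_values, function(m) any(m1_values == -m), TRUE)))
    abort_config("m1_values must contain 0 and a +/- pair")
  structure(list(tr = tr, n_proj = n_proj, n_readout = n_readout,
                 echo_fraction = echo_fraction, idx_echo = idx_echo,
                 matrix = matrix, fov = fov, sampling_bw = sampling_bw,
                 te = te, m1_values = m1_values,
                 n_encodings = length(m1_values),
                 wait_between_encodings = wait_between_encodings),
            class = "acq_config")
}

#' Maximum encoding velocity from the first gradient moments
#'
#' The velocity producing an encoding phase of +/- pi: `VENC = 1/(2*max|m1|)`
#' with m1 the reduced first moment gamma*M1/2pi in s/m. For m1 = 0.3 s/m
#' this gives 1.667 m/s (1.7 m/s at the printed precision).
#'
#' @param m1_values reduced first gradient moments (s/m).
#' @return VENC in m/s.
#' @export
venc_from_m1 <- function(m1_values) {
  m <- max(abs(m1_values))
  if (m <= 0) abort_config("need a non-zero first moment")
  1 / (2 * m)
}

#' Total scan duration of the protocol
#'
#' `n_encodings * n_proj * TR` plus the waits between encodings.
#'
#' @param acq an [acq_config()].
#' @return duration in seconds.
#' @export
scan_duration <- function(acq) {
  ne <- acq$n_encodings
  ne * acq$n_proj * acq$tr + (ne - 1) * acq$wait_between_encodings
}

#' Golden-angle projection list
#'
#' Angle `i` (0-based) equals `(theta0 + i * 180/phi) mod 360` degrees with
#' `phi` the golden ratio, i.e. consecutive projections advance by the golden
#' angle of about 111.246 degrees. The full circle is used because partial
#' echoes make theta and theta + 180 non-equivalent.
#'
#' @param n_proj number of projections.
#' @param theta0 initial angle (degrees).
#' @return numeric vector of angles in degrees, in `[0, 360)`.
#' @export
golden_angles <- function(n_proj, theta0 = 0) {
  if (n_proj < 1) abort_config("n_proj must be >= 1")
  delta <- 180 / golden_ratio
  (theta0 + (seq_len(n_proj) - 1) * delta) %% 360
}

#' Heartbeat-interleaved sublist ordering of the golden-angle list
#'
#' Sorts a monotone golden-angle list into `N = round(t_rr_est / tr)`
#' interleaved sublists of `K = floor(n_proj / N)` projections each, so that
#' projections acquired one estimated heartbeat apart are consecutive members
#' of one golden-angle sublist. Retrospectively binned projections from one
#' cardiac phase then form a near-uniform golden-angle set. When `N` does not
#' divide `n_proj` the remaining acquisitions continue the interleave cycle,
#' giving the first `n_proj - N*K` sublists one extra member; the permutation
#' stays a bijection.
#'
#' @param n_proj number of projections.
#' @param tr repetition time (s).
#' @param t_rr_est estimated mean cardiac interval (s).
#' @return an object of class `sublist_plan` with elements `n_sublists`,
#'   `projections_per_sublist`, and `permutation` (1-based map from
#'   acquisition index to golden-sequence index).
#' @export
sublist_plan <- function(n_proj, tr, t_rr_est) {
  if (n_proj < 1) abort_config("n_proj must be >= 1")
  if (t_rr_est <= tr) abort_config("t_rr_est must exceed tr")
  N <- round(t_rr_est / tr)
  K <- floor(n_proj / N)
  if (K < 1) abort_config("fewer projections than sublists")
  r <- n_proj - N * K
  # sublist s (0-based) holds golden indices offset_s .. offset_s + K_s - 1,
  # K_s = K + (s < r)
  offs <- (0:(N - 1)) * K + pmin(0:(N - 1), r)
  j <- 0:(n_proj - 1)
  perm <- integer(n_proj)
  main <- j < N * K
  perm[main] <- offs[(j[main] %% N) + 1] + j[main] %/% N
  if (r > 0) {
    m <- j[!main] - N * K
    perm[!main] <- offs[m + 1] + K
  }
  structure(list(n_sublists = N, projections_per_sublist = K,
                 n_proj = n_proj, tr = tr, t_rr_est = t_rr_est,
                 delta_theta = 180 / golden_ratio,
                 permutation = perm + 1L),
            class = "sublist_plan")
}

#' @export
print.sublist_plan <- function(x, ...) {
  cat(sprintf("<sublist_plan> %d projections in %d sublists of %d (+%d remainder)\n",
              x$n_proj, x$n_sublists, x$projections_per_sublist,
              x$n_proj - x$n_sublists * x$projections_per_sublist))
  invisible(x)
}

#' @export
tidy.sublist_plan <- function(x, ...) {
  N <- x$n_sublists; K <- x$projections_per_sublist
  r <- x$n_proj - N * K
  offs <- (0:(N - 1)) * K + pmin(0:(N - 1), r)
  tibble(acquisition = seq_len(x$n_proj),
         golden_index = x$permutation,
         sublist = findInterval(x$permutation - 1, offs))
}

#' Asymmetric radial sample positions
#'
#' Builds the k-space trajectory for a set of projection angles: projection
#' at angle theta samples `k = (idx - idx_echo) * dk * (cos theta, sin theta)`
#' with `dk` one cycle per FOV, where `idx_echo = round(echo_fraction *
#' n_readout)` places the gradient echo asymmetrically in the readout (10 %
#' by default). Sample times advance by `1/sampling_bw` within a readout and
#' by TR between projections; relative to excitation the echo sample is at TE.
#'
#' @param acq an [acq_config()].
#' @param angles projection angles in degrees; defaults to the sublist-sorted
#'   golden-angle list when `plan` is given, else the plain golden-angle list.
#' @param plan optional [sublist_plan()] used to order the golden-angle list.
#' @param theta0 initial angle (degrees).
#' @return an object of class `radial_trajectory`: list with `angles`
#'   (degrees, per projection), `kx`, `ky` (`n_readout x n_proj` matrices,
#'   cycles/FOV), `t_read` (readout times relative to excitation, s),
#'   `t_proj` (projection start offsets from encoding start, s), and
#'   `delays = c(t_x, t_y)` (s).
#' @export
radial_trajectory <- function(acq, angles = NULL, plan = NULL, theta0 = 0) {
  if (is.null(angles)) {
    base <- golden_angles(acq$n_proj, theta0)
    angles <- if (is.null(plan)) base else {
      if (plan$n_proj != acq$n_proj) abort_config("plan/acq n_proj mismatch")
      base[plan$permutation]
    }
  }
  nr <- acq$n_readout
  idx <- 0:(nr - 1)
  c_m <- idx - acq$idx_echo                      # cycles/FOV
  th <- angles * pi / 180
  kx <- outer(c_m, cos(th))
  ky <- outer(c_m, sin(th))
  structure(list(angles = angles, kx = kx, ky = ky,
                 t_read = acq$te + (idx - acq$idx_echo) / acq$sampling_bw,
                 t_proj = (seq_along(angles) - 1) * acq$tr,
                 delays = c(t_x = 0, t_y = 0), acq = acq),
            class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("<radial_trajectory> %d projections x %d samples, echo index %d, delays (%.3g, %.3g) us\n",
              length(x$angles), nrow(x$kx), x$acq$idx_echo,
              x$delays[1] * 1e6, x$delays[2] * 1e6))
  invisible(x)
}

#' Tidy a radial trajectory into a sample table
#'
#' @param x a `radial_trajectory`.
#' @param ... unused.
#' @return tibble with one row per sample: projection, sample index (1-based),
#'   `k_x`, `k_y` (cycles/FOV) and time from encoding start (s).
#' @export
tidy.radial_trajectory <- function(x, ...) {
  nr <- nrow(x$kx); np <- ncol(x$kx)
  tibble(projection = rep(seq_len(np), each = nr),
         sample = rep(seq_len(nr), times = np),
         k_x = as.vector(x$kx), k_y = as.vector(x$ky),
         t = rep(x$t_proj, each = nr) +
           rep(x$t_read - x$t_read[x$acq$idx_echo + 1], times = np) +
           (x$acq$idx_echo / x$acq$sampling_bw))
}

# per-projection k shift (cycles/FOV) caused by per-axis gradient delays:
# during the constant-slope readout dk/dt = dk * bandwidth along the readout
# direction, so an axis delay translates the whole line by
# bandwidth * delay * (direction component on that axis).
delay_shift <- function(traj, t_x, t_y) {
  th <- traj$angles * pi / 180
  bw <- traj$acq$sampling_bw
  list(sx = bw * t_x * cos(th), sy = bw * t_y * sin(th))
}

#' Apply or correct gradient delays on a radial trajectory
#'
#' A delay of the physical x (y) gradient translates every sample of a
#' projection along x (y) by `sampling_bw * t_x * cos(theta)`
#' (`sampling_bw * t_y * sin(theta)`) cycles/FOV; this first-order model
#' mirrors the dephase-area correction used on the scanner.
#' `correct_gradient_delays()` applies the inverse translation, so applying
#' then correcting with the same delays is the identity.
#'
#' @param traj a [radial_trajectory()].
#' @param t_x,t_y per-axis gradient delays (s).
#' @return the trajectory with shifted sample positions; the cumulative
#'   applied delay is tracked in `$delays`.
#' @export
apply_gradient_delays <- function(traj, t_x, t_y) {
  if (!is.finite(t_x) || !is.finite(t_y)) abort_config("delays must be finite")
  s <- delay_shift(traj, t_x, t_y)
  traj$kx <- sweep(traj$kx, 2, s$sx, "+")
  traj$ky <- sweep(traj$ky, 2, s$sy, "+")
  traj$delays <- traj$delays + c(t_x, t_y)
  traj
}

#' @rdname apply_gradient_delays
#' @export
correct_gradient_delays <- function(traj, t_x, t_y) {
  apply_gradient_delays(traj, -t_x, -t_y)
}

#' Export a trajectory as CSV
#'
#' Writes the tidy per-sample table (projection, sample, k_x, k_y, t).
#'
#' @param traj a [radial_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(tidy(traj), path, row.names = FALSE)
  invisible(path)
}
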