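# MR forward model: simulate flow-encoded radial k-space from the dynamic
# phantom, with cardiac-interval variability, respiratory bursts, inflow
# enhancement, off-resonance, gradient delays and complex Gaussian noise.
#
# The forward model splits the rasterized image into a static background
# (tissue ellipse, off-resonance below ~20 Hz truncated to zero) evaluated by
# the fast type-2 NUFFT, and a small dynamic box around the vessel (pulsating
# lumen plus the off-resonance blob) evaluated exactly per projection by a
# phase-recurrence non-uniform DFT (cpp_line_forward). The vessel state is
# quantized to `cardiac_bins` cardiac-phase bins for caching; rigid
# respiratory translation enters as a k-space phase ramp, which is exact.

# dynamic-box geometry: pixel index ranges (1-based) and coordinates
dyn_box <- function(phantom, acq) {
  n <- phantom$grid_hi
  fov <- acq$fov
  hw_m <- 1.6 * lumen_radius(phantom$a_peak)
  if (phantom$b0_peak > 20)
    hw_m <- max(hw_m, phantom$b0_sigma * sqrt(2 * log(phantom$b0_peak / 20)))
  hw_px <- ceiling(hw_m / fov * n) + 1
  cpx <- round(phantom$vessel_center / fov * n) + n / 2     # 0-based
  ix <- max(0, cpx[1] - hw_px):min(n - 1, cpx[1] + hw_px)
  iy <- max(0, cpx[2] - hw_px):min(n - 1, cpx[2] + hw_px)
  g <- grid_coords(n)
  list(ix = ix + 1, iy = iy + 1,
       x = rep(g[ix + 1], times = length(iy)),
       y = rep(g[iy + 1], each = length(ix)))
}

# complex pixel values of the dynamic box for one cardiac state and encoding
box_values <- function(phantom, a, q, m1, venc, fov, box, cov_e_box, n) {
  gx <- unique(box$x); gy <- unique(box$y)
  nx <- length(gx); ny <- length(gy)
  R <- lumen_radius(a) / fov
  ctr <- phantom$vessel_center / fov
  h <- 0.5 / n
  dx <- outer(gx - ctr[1], rep(1, ny))
  dy <- outer(rep(1, nx), gy - ctr[2])
  d <- sqrt(dx^2 + dy^2)
  cov <- (d <= R - h * sqrt(2)) * 1.0
  edge <- which(d < R + h * sqrt(2) & cov == 0)
  if (length(edge)) {
    sub <- 8
    off <- ((seq_len(sub) - 0.5) / sub - 0.5) / n
    ox <- rep(off, times = sub); oy <- rep(off, each = sub)
    inside <- outer(dx[edge], ox, "+")^2 + outer(dy[edge], oy, "+")^2 <= R^2
    cov[edge] <- rowMeans(inside)
  }
  vbar <- q / a
  v <- 2 * vbar * pmax(1 - (d / R)^2, 0)
  mag <- phantom$lumen_signal * (1 + phantom$inflow_beta * vbar / venc)
  val <- mag * exp(2i * pi * m1 * v)
  tissue <- cov_e_box * phantom$tissue_signal
  tissue * (1 - cov) + cov * val
}

# cardiac-interval sequence and relative-phase lookup over [0, total]
draw_beats <- function(phantom, total) {
  lo <- phantom$t_rr_mean - 4 * phantom$t_rr_sd
  hi <- phantom$t_rr_mean + 4 * phantom$t_rr_sd
  n <- ceiling((total + 1) / max(lo, 1e-3)) + 2
  iv <- pmin(pmax(rnorm(n, phantom$t_rr_mean, phantom$t_rr_sd), lo), hi)
  cumsum(c(0, iv))
}

resp_profile <- function(phantom, t, total) {
  if (phantom$resp_shift == 0 && phantom$resp_signal_frac == 0)
    return(list(prof = numeric(length(t)),
                intervals = tibble(start = numeric(0), end = numeric(0))))
  bs <- seq(phantom$resp_phase0, total + phantom$resp_period,
            by = phantom$resp_period)
  k <- findInterval(t, bs)
  tau <- t - bs[pmax(k, 1)]
  prof <- ifelse(k >= 1 & tau < phantom$resp_motion_duration,
                 sin(pi * tau / phantom$resp_motion_duration)^2, 0)
  list(prof = prof,
       intervals = tibble(start = bs,
                          end = bs + phantom$resp_motion_duration))
}

#' Simulate a retrospectively gated radial flow acquisition
#'
#' Runs the full MR forward model over all velocity encodings of `acq`: for
#' each projection the phantom state at the acquisition time is transformed to
#' the projection's k-space positions (off-resonance phase accruing from
#' excitation, exactly), respiration is applied as a rigid-translation phase
#' ramp plus a small through-slice signal modulation, an approach-to-steady-
#' state transient scales the start of each encoding, and circular complex
#' Gaussian noise is added. Timestamps include the waits between encodings.
#'
#' @param phantom a [phantom_config()].
#' @param acq an [acq_config()].
#' @param traj a [radial_trajectory()]; defaults to the sublist-sorted
#'   golden-angle trajectory using `phantom$t_rr_mean` as the interval
#'   estimate (apply gradient delays beforehand to model delay errors).
#' @param seed RNG seed; the simulation is bit-reproducible for a fixed seed.
#' @return an object of class `projection_set`: list with `kspace` (one
#'   `n_readout x n_proj` complex matrix per encoding), `traj`, `acq`,
#'   `phantom`, `venc`, `enc_starts` (s), `proj_times` (matrix, absolute
#'   time of each projection per encoding), and `ground_truth` (trigger
#'   times, respiratory intervals, sampled waveforms, per-projection state,
#'   true off-resonance map, `pwv_true`).
#' @export
simulate_acquisition <- function(phantom, acq, traj = NULL,
                                 seed = phantom$seed) {
  if (is.null(traj))
    traj <- radial_trajectory(
      acq, plan = sublist_plan(acq$n_proj, acq$tr, phantom$t_rr_mean))
  if (ncol(traj$kx) != acq$n_proj || nrow(traj$kx) != acq$n_readout)
    abort_config("trajectory and acquisition are inconsistent")
  set.seed(seed)
  ne <- acq$n_encodings
  n <- phantom$grid_hi
  fov <- acq$fov
  venc <- venc_from_m1(acq$m1_values)
  enc_len <- acq$n_proj * acq$tr
  enc_starts <- (0:(ne - 1)) * (enc_len + acq$wait_between_encodings)
  total <- ne * enc_len + (ne - 1) * acq$wait_between_encodings

  triggers <- draw_beats(phantom, total)
  phase_of <- function(t) {
    i <- findInterval(t, triggers)
    (t - triggers[i]) / (triggers[i + 1] - triggers[i])
  }
  # Systole has a fixed absolute duration (diastole absorbs the RR
  # variability), so the waveform is evaluated at time-since-trigger
  # normalized by the mean interval, clamped into the diastolic plateau.
  phase_used <- function(t) {
    i <- findInterval(t, triggers)
    pmin((t - triggers[i]) / phantom$t_rr_mean, 0.75)
  }
  resp <- resp_profile(phantom, 0, total)   # intervals only; profile per enc

  # static background with the dynamic box zeroed
  cov_e <- ellipse_coverage(0, 0, phantom$tissue_semiaxes[1] / fov,
                            phantom$tissue_semiaxes[2] / fov, n)
  s_ref <- sum(cov_e)                       # tissue k-centre magnitude scale
  box <- dyn_box(phantom, acq)
  cov_e_box <- cov_e[box$ix, box$iy]
  bg <- cov_e * phantom$tissue_signal
  bg[box$ix, box$iy] <- 0
  s_bg <- matrix(nufft_forward(bg, as.vector(traj$kx), as.vector(traj$ky)),
                 acq$n_readout, acq$n_proj)

  b0_hz <- b0_field_true(phantom, n, fov)
  omega_box <- 2 * pi * as.vector(b0_hz[box$ix, box$iy])
  sh <- delay_shift(traj, traj$delays[1], traj$delays[2])
  th <- traj$angles * pi / 180
  nb <- phantom$cardiac_bins
  t0 <- acq$te - acq$idx_echo / acq$sampling_bw
  dt <- 1 / acq$sampling_bw
  sd_comp <- phantom$noise_sd * s_ref / sqrt(2)

  kspace <- vector("list", ne)
  proj_times <- matrix(0, acq$n_proj, ne)
  gt_rows <- vector("list", ne)
  for (e in seq_len(ne)) {
    m1 <- acq$m1_values[e]
    t_abs <- enc_starts[e] + traj$t_proj
    proj_times[, e] <- t_abs
    ph <- phase_of(t_abs)
    pu <- phase_used(t_abs)
    bins <- pmin(floor(pu * nb), nb - 1)
    sig <- s_bg
    for (b in sort(unique(bins))) {
      j <- which(bins == b)
      w <- cardiac_waveforms(phantom, (b + 0.5) / nb)
      vals <- box_values(phantom, w$a, w$q, m1, venc, fov, box, cov_e_box, n)
      sig[, j] <- sig[, j] +
        cpp_line_forward(as.complex(as.vector(vals)), box$x, box$y,
                         omega_box, cos(th[j]), sin(th[j]),
                         sh$sx[j], sh$sy[j], -acq$idx_echo, 1,
                         acq$n_readout, t0, dt)
    }
    rp <- resp_profile(phantom, t_abs, total)
    dy_sh <- phantom$resp_shift * rp$prof / fov
    if (any(dy_sh != 0))
      sig <- sig * exp(-2i * pi * sweep(traj$ky, 2, dy_sh, "*"))
    amp <- (1 + phantom$resp_signal_frac * rp$prof) *
      (1 - phantom$transient_frac * exp(-traj$t_proj / phantom$transient_tau))
    sig <- sweep(sig, 2, amp, "*")
    if (sd_comp > 0) {
      nsamp <- length(sig)
      sig <- sig + complex(real = rnorm(nsamp, 0, sd_comp),
                           imaginary = rnorm(nsamp, 0, sd_comp))
    }
    kspace[[e]] <- sig
    wtr <- cardiac_waveforms(phantom, pu)
    gt_rows[[e]] <- tibble(encoding = e, projection = seq_along(t_abs),
                           time = t_abs, phase = ph, a = wtr$a, q = wtr$q,
                           in_resp = rp$prof > 0)
  }

  wave <- cardiac_waveforms(phantom, (0:511) / 512)
  ground_truth <- list(
    trigger_times = triggers[triggers <= total],
    resp_intervals = resp$intervals,
    pwv_true = phantom$pwv_true,
    waveforms = wave,
    b0_hz_true = b0_hz,
    per_projection = dplyr::bind_rows(gt_rows))

  structure(list(kspace = kspace, traj = traj, acq = acq, phantom = phantom,
                 venc = venc, enc_starts = enc_starts,
                 proj_times = proj_times, s_ref = s_ref, seed = seed,
                 ground_truth = ground_truth),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %d encodings x %d projections x %d samples (seed %d)\n",
              length(x$kspace), x$acq$n_proj, x$acq$n_readout, x$seed))
  invisible(x)
}

#' Simulate a two-echo field-mapping probe pair
#'
#' Acquires two static (diastolic, flow-compensated) radial data sets whose
#' echo times differ by `delta_te`, with the phantom's off-resonance field
#' applied exactly. Reconstructing both and taking the phase of the conjugate
#' product recovers the field map (see [b0_map()]).
#'
#' @param phantom a [phantom_config()].
#' @param acq an [acq_config()]; only geometry/timing fields are used.
#' @param n_spokes number of golden-angle projections per echo.
#' @param delta_te echo-time difference (s).
#' @param delays per-axis gradient delays applied to the probe trajectory (s).
#' @param seed RNG seed.
#' @return list with complex sample matrices `s1`, `s2`, the probe
#'   trajectory `traj`, and `delta_te`.
#' @export
simulate_b0_probe <- function(phantom, acq, n_spokes = 600, delta_te = 0.5e-3,
                              delays = c(0, 0), seed = phantom$seed + 77L) {
  set.seed(seed)
  acq2 <- acq
  acq2$n_proj <- as.integer(n_spokes)
  traj <- radial_trajectory(acq2)
  if (any(delays != 0))
    traj <- apply_gradient_delays(traj, delays[1], delays[2])
  n <- phantom$grid_hi; fov <- acq$fov
  cov_e <- ellipse_coverage(0, 0, phantom$tissue_semiaxes[1] / fov,
                            phantom$tissue_semiaxes[2] / fov, n)
  s_ref <- sum(cov_e)
  box <- dyn_box(phantom, acq)
  cov_e_box <- cov_e[box$ix, box$iy]
  bg <- cov_e * phantom$tissue_signal
  bg[box$ix, box$iy] <- 0
  s_bg <- nufft_forward(bg, as.vector(traj$kx), as.vector(traj$ky))
  omega_box <- 2 * pi * as.vector(b0_field_true(phantom, n, fov)[box$ix, box$iy])
  vals <- box_values(phantom, phantom$a_dia, 0, 0, venc_from_m1(acq$m1_values),
                     fov, box, cov_e_box, n)
  sh <- delay_shift(traj, traj$delays[1], traj$delays[2])
  th <- traj$angles * pi / 180
  t0 <- acq$te - acq$idx_echo / acq$sampling_bw
  dt <- 1 / acq$sampling_bw
  mk <- function(t_start) {
    s <- matrix(s_bg, acq2$n_readout, acq2$n_proj) +
      cpp_line_forward(as.complex(as.vector(vals)), box$x, box$y, omega_box,
                       cos(th), sin(th), sh$sx, sh$sy, -acq$idx_echo, 1,
                       acq2$n_readout, t_start, dt)
    sd_comp <- phantom$noise_sd * s_ref / sqrt(2)
    if (sd_comp > 0)
      s <- s + complex(real = rnorm(length(s), 0, sd_comp),
                       imaginary = rnorm(length(s), 0, sd_comp))
    s
  }
  list(s1 = mk(t0), s2 = mk(t0 + delta_te), traj = traj, delta_te = delta_te)
}
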