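# Time-segmented conjugate-phase reconstruction: off-resonance-corrected
# adjoint with the exponential exp(-i*omega(r)*t_j) approximated by a
# least-squares combination of a few segment-centre demodulations.

# Least-squares temporal-interpolation coefficients: for each unique sample
# time t find c_L(t) minimizing the histogram-weighted error
# | exp(-i*w*t) - sum_L c_L exp(-i*w*t_L) | over the field's frequencies.
cp_coefficients <- function(omega_vals, t_seg, t_unique, n_bins = 33) {
  rng <- range(omega_vals)
  if (diff(rng) == 0) {
    grid <- rng[1]; h <- 1
  } else {
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    cnt <- tabulate(findInterval(omega_vals, br, rightmost.closed = TRUE),
                    nbins = n_bins)
    grid <- (br[-1] + br[-length(br)]) / 2
    keep <- cnt > 0
    grid <- grid[keep]; h <- cnt[keep]
  }
  E <- exp(-1i * outer(grid, t_seg))            # Q x L
  FF <- exp(-1i * outer(grid, t_unique))        # Q x Nt
  A <- Conj(t(E)) %*% (h * E)
  B <- Conj(t(E)) %*% (h * FF)
  # least-norm solve via SVD pseudo-inverse (A can be rank deficient when
  # the field has few distinct values)
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  Ainv <- sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * Conj(t(sv$u[, pos, drop = FALSE])))
  Ainv %*% B                                     # L x Nt
}

#' Conjugate-phase off-resonance-corrected reconstruction
#'
#' Approximates the off-resonance-corrected adjoint
#' `rho(r) = sum_j w_j s_j exp(-i*omega(r)*t_j) exp(+2i*pi*k_j.r)` by time
#' segmentation: the readout is split into `n_segments` reference times
#' `t_L`, the exponential is least-squares interpolated between them, and the
#' image is `sum_L exp(-i*omega(r)*t_L) * adjoint(w * s * c_L(t_j))`. With a
#' zero field map this reduces exactly to [gridded_adjoint()].
#'
#' @param samples complex k-space samples.
#' @param kx,ky sample positions (cycles/FOV).
#' @param t per-sample times relative to excitation (s).
#' @param weights density weights ([pipe_dcf()] result or numeric vector).
#' @param omega off-resonance map (rad/s), `matrix x matrix`.
#' @param n_segments number of time segments.
#' @param matrix output image edge (pixels).
#' @param os,width,beta gridding parameters.
#' @return complex `matrix x matrix` image.
#' @export
conjugate_phase_recon <- function(samples, kx, ky, t, weights, omega,
                                  n_segments = 8, matrix, os = 2, width = 4,
                                  beta = kb_beta(width, os)) {
  if (n_segments < 1) abort_config("n_segments must be >= 1")
  if (is.null(omega) || all(omega == 0))
    return(gridded_adjoint(samples, kx, ky, weights, matrix, os, width, beta))
  if (!all(dim(omega) == c(matrix, matrix)))
    abort_config("field-map geometry does not match the matrix")
  w <- if (inherits(weights, "density_weights")) weights$w else weights
  tr <- range(t)
  t_seg <- tr[1] + (seq_len(n_segments) - 0.5) * diff(tr) / max(n_segments, 1)
  if (n_segments == 1) t_seg <- mean(tr)
  tu <- sort(unique(round(t, 12)))
  C <- cp_coefficients(as.vector(omega), t_seg, tu)
  idx <- match(round(t, 12), tu)
  out <- matrix(0 + 0i, matrix, matrix)
  for (l in seq_len(n_segments)) {
    cl <- C[l, idx]
    out <- out + exp(-1i * omega * t_seg[l]) *
      gridded_adjoint(samples * cl, kx, ky, w, matrix, os, width, beta)
  }
  out
}

# exact (slow) evaluation, kept as the oracle for the segmented version
conjugate_phase_exact <- function(samples, kx, ky, t, weights, omega) {
  w <- if (inherits(weights, "density_weights")) weights$w else weights
  n <- nrow(omega)
  nudft_adjoint_direct(samples * w, kx, ky, n, omega = omega, t = t)
}
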