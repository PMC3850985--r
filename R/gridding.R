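# Kaiser-Bessel gridding reconstruction: Pipe's iterative density
# compensation and the gridded adjoint non-uniform Fourier transform.

#' Iterative (Pipe) density compensation weights
#'
#' Fixed-point iteration `w <- w / (w (*) kernel)` evaluated at the sample
#' locations, starting from `w = 1`. At the fixed point the kernel-smoothed
#' sampling density is flat over the sampled region, which is the density
#' compensation required before gridding. The convolution is evaluated by
#' spreading onto the oversampled grid and interpolating back with the same
#' Kaiser-Bessel kernel.
#'
#' @param kx,ky sample positions (cycles/FOV).
#' @param matrix reconstruction grid edge (pixels).
#' @param os grid oversampling factor.
#' @param width Kaiser-Bessel kernel width (oversampled-grid units).
#' @param beta Kaiser-Bessel shape parameter.
#' @param n_iterations number of fixed-point iterations.
#' @return an object of class `density_weights`: list with `w` (one
#'   nonnegative weight per sample) and `convergence`
#'   (`max |w (*) kernel - 1|` per iteration over the samples).
#' @export
pipe_dcf <- function(kx, ky, matrix, os = 2, width = 4,
                     beta = kb_beta(width, os), n_iterations = 15) {
  if (!length(kx)) abort_config("need at least one sample")
  G <- os * matrix
  gx <- kx * os + G / 2
  gy <- ky * os + G / 2
  w <- rep(1, length(kx))
  conv <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    d <- as.vector(cpp_kb_convolve_at(w, gx, gy, G, width, beta))
    if (any(d <= 0)) {
      warning("zero denominator in Pipe iteration; clamped")
      d <- pmax(d, .Machine$double.eps * max(d))
    }
    conv[it] <- max(abs(d - 1))
    w <- w / d
  }
  structure(list(w = w, convergence = conv, matrix = matrix, os = os,
                 width = width, beta = beta, n_iterations = n_iterations),
            class = "density_weights")
}

#' @export
print.density_weights <- function(x, ...) {
  cat(sprintf("<density_weights> %d samples, %d iterations, final max|w*C - 1| = %.3g\n",
              length(x$w), x$n_iterations, tail(x$convergence, 1)))
  invisible(x)
}

#' Gridded adjoint non-uniform Fourier transform
#'
#' Density-weighted Kaiser-Bessel convolution of the samples onto a
#' 2x-oversampled Cartesian grid, inverse FFT, deapodization, and central
#' crop. Approximates the direct adjoint
#' `rho(x) = sum_j w_j s_j exp(+2i*pi*k_j.x)` evaluated at the pixel
#' positions; linear in the samples.
#'
#' @param samples complex k-space samples.
#' @param kx,ky sample positions (cycles/FOV).
#' @param weights a [pipe_dcf()] result, or a numeric weight vector.
#' @param matrix output image edge (pixels).
#' @param os,width,beta gridding parameters (must match `weights` if those
#'   came from [pipe_dcf()]).
#' @return complex `matrix x matrix` image.
#' @export
gridded_adjoint <- function(samples, kx, ky, weights, matrix, os = 2,
                            width = 4, beta = kb_beta(width, os)) {
  w <- if (inherits(weights, "density_weights")) weights$w else weights
  if (length(w) != length(samples) || length(kx) != length(samples))
    abort_config("samples, positions and weights must have equal length")
  G <- os * matrix
  grid <- cpp_kb_spread(as.complex(samples * w), kx * os + G / 2,
                        ky * os + G / 2, G, width, beta)
  img <- ift2(grid)
  a <- kb_apodization(G, width, beta)
  img <- img / outer(a, a)
  crop_center(img, matrix)
}

#' Zero-fill an image to a larger matrix by symmetric k-space padding
#'
#' Fourier-transforms the image, pads the spectrum symmetrically with zeros,
#' and transforms back; this interpolates the image onto the finer grid
#' without adding information (e.g. 160 -> 256, pixel 150 um -> 93.75 um).
#'
#' @param img complex image.
#' @param n_out output edge (pixels).
#' @return complex `n_out x n_out` image.
#' @export
zero_fill <- function(img, n_out = 256) {
  n <- nrow(img)
  if (n_out == n) return(img)
  if (n_out < n) abort_config("n_out must be >= input size")
  # ift2(ft2(x)) = n^2 * x, so dividing by n^2 keeps pixel amplitudes
  ift2(pad_center(ft2(img), n_out)) / (n * n)
}
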