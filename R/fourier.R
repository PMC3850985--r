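# Centred 2-D Fourier helpers and the Kaiser-Bessel apodization profile.
#
# Conventions used throughout the package:
#   * k-space coordinates are in cycles per field of view, so the Cartesian
#     reconstruction grid has unit spacing;
#   * image coordinates are in FOV units, pixel i (0-based) of an n-pixel
#     image sits at x = (i - n/2)/n, i.e. the DC pixel is at index n/2;
#   * forward transform uses exp(-2*pi*1i*k.x), adjoint exp(+2*pi*1i*k.x).
# All grids are even-sized, so fftshift is its own inverse.

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2)), drop = FALSE]
}

# centred forward/inverse 2-D DFT (inverse is unnormalised, like stats::fft)
ft2 <- function(x) fftshift2(fft(fftshift2(x)))
ift2 <- function(x) fftshift2(fft(fftshift2(x), inverse = TRUE))

# Default Kaiser-Bessel shape parameter for a given kernel width and grid
# oversampling factor (the standard minimum-aliasing-error choice).
kb_beta <- function(width = 4, os = 2) {
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

kb_eval <- function(u, width, beta) {
  t <- 1 - (2 * u / width)^2
  out <- numeric(length(u))
  ok <- t >= 0
  out[ok] <- besselI(beta * sqrt(t[ok]), 0)
  out
}

# Image-domain apodization of the KB kernel on a length-G grid: the continuous
# Fourier transform of the kernel evaluated at the image frequencies
# f_i = (i - G/2)/G (cycles per grid sample). Cached per (G, width, beta).
.kb_cache <- new.env(parent = emptyenv())

kb_apodization <- function(G, width = 4, beta = kb_beta(width)) {
  key <- sprintf("%d_%g_%.10g", G, width, beta)
  if (!is.null(.kb_cache[[key]])) return(.kb_cache[[key]])
  u <- seq(-width / 2, width / 2, length.out = 4097)
  ku <- kb_eval(u, width, beta)
  f <- ((0:(G - 1)) - G / 2) / G
  a <- as.vector(cos(2 * pi * outer(f, u)) %*% ku) * (u[2] - u[1])
  .kb_cache[[key]] <- a
  a
}

# crop the central n x n block of a G x G matrix
crop_center <- function(x, n) {
  G <- nrow(x)
  i <- (G - n) / 2 + seq_len(n)
  x[i, i, drop = FALSE]
}

# embed an n x n matrix centred in a G x G zero matrix
pad_center <- function(x, G) {
  n <- nrow(x)
  out <- matrix(0 + 0i, G, G)
  i <- (G - n) / 2 + seq_len(n)
  out[i, i] <- x
  out
}

#' Fast forward non-uniform Fourier transform (type 2)
#'
#' Evaluates `sum_p img[p] * exp(-2i*pi*(kx*x_p + ky*y_p))` at arbitrary
#' k-space positions via deapodized zero-padded FFT followed by Kaiser-Bessel
#' interpolation. Image pixel `i` (0-based) is at `x = (i - n/2)/n` FOV units;
#' `kx`, `ky` are in cycles per FOV and must satisfy `|k| < n/2`.
#'
#' @param img complex (or numeric) square matrix.
#' @param kx,ky k-space sample positions, cycles/FOV.
#' @param os grid oversampling factor.
#' @param width Kaiser-Bessel kernel width in oversampled-grid units.
#' @param beta Kaiser-Bessel shape parameter.
#' @return complex vector of samples, one per (kx, ky) pair.
#' @export
nufft_forward <- function(img, kx, ky, os = 2, width = 4, beta = kb_beta(width, os)) {
  n <- nrow(img)
  if (ncol(img) != n) abort_config("nufft_forward: image must be square")
  if (length(kx) != length(ky)) abort_config("nufft_forward: kx/ky length mismatch")
  G <- os * n
  a <- kb_apodization(G, width, beta)
  ax <- a[G / 2 - n / 2 + seq_len(n)]
  pad <- pad_center(img / outer(ax, ax), G)
  S <- ft2(pad)
  as.vector(cpp_kb_interp(S, kx * os + G / 2, ky * os + G / 2, width, beta))
}

# Slow exact counterparts (oracles). Image convention as above.
nudft_forward_direct <- function(img, kx, ky) {
  n <- nrow(img)
  xy <- ((0:(n - 1)) - n / 2) / n
  x <- rep(xy, times = n)   # row index = x
  y <- rep(xy, each = n)
  as.vector(cpp_nudft_forward(as.complex(as.vector(img)), x, y, kx, ky))
}

nudft_adjoint_direct <- function(samples, kx, ky, n, omega = NULL, t = NULL) {
  xy <- ((0:(n - 1)) - n / 2) / n
  x <- rep(xy, times = n)
  y <- rep(xy, each = n)
  om <- if (is.null(omega)) numeric(0) else as.vector(omega)
  tt <- if (is.null(t)) numeric(0) else t
  v <- as.vector(cpp_nudft_adjoint(as.complex(samples), kx, ky, x, y, om, tt))
  matrix(v, n, n)
}
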