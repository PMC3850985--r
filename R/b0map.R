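# Two-echo off-resonance (B0) mapping with quality-guided phase unwrapping.

#' Off-resonance map from a two-echo image pair
#'
#' The phase difference between two images whose echo times differ by
#' `delta_te` is `dphi(r) = Arg(conj(rho1) * rho2) = delta_omega0(r) * dTE`,
#' so the off-resonance field is `delta_omega0 = dphi / delta_te` (rad/s).
#' The map is restricted to pixels above a magnitude floor; when neighbouring
#' phase jumps exceed pi inside the mask, 2-D quality-guided spatial
#' unwrapping (quality = magnitude product) is applied first.
#'
#' @param img1,img2 complex images of the two echoes.
#' @param delta_te echo-time difference (s).
#' @param mag_floor mask threshold as a fraction of the robust (99th
#'   percentile) magnitude.
#' @return an object of class `b0_map`: list with `omega` (rad/s), `hz`,
#'   `mask`, `delta_te`, `unwrapped` (logical).
#' @export
b0_map <- function(img1, img2, delta_te, mag_floor = 0.1) {
  if (delta_te <= 0) abort_config("delta_te must be positive")
  if (!all(dim(img1) == dim(img2))) abort_config("image geometries differ")
  dphi <- Arg(Conj(img1) * img2)
  q <- Mod(img1) * Mod(img2)
  mask <- q > mag_floor * quantile(q, 0.99)
  wrap <- function(m) {
    dx <- abs(diff(m)); mm <- mask[-1, ] & mask[-nrow(mask), ]
    dy <- abs(t(diff(t(m)))); mmy <- mask[, -1] & mask[, -ncol(mask)]
    any(dx[mm] > pi) || any(dy[mmy] > pi)
  }
  unwrapped <- FALSE
  if (wrap(dphi)) {
    dphi <- cpp_unwrap2d(dphi, q, mask * 1L)
    unwrapped <- TRUE
  }
  omega <- ifelse(mask, dphi / delta_te, 0)
  structure(list(omega = omega, hz = omega / (2 * pi), mask = mask,
                 delta_te = delta_te, unwrapped = unwrapped),
            class = "b0_map")
}

#' @export
print.b0_map <- function(x, ...) {
  cat(sprintf("<b0_map> %dx%d, dTE = %.3g ms, range %.0f..%.0f Hz%s\n",
              nrow(x$hz), ncol(x$hz), x$delta_te * 1e3,
              min(x$hz), max(x$hz),
              if (x$unwrapped) " (unwrapped)" else ""))
  invisible(x)
}

#' Write an off-resonance map as NIfTI
#'
#' @param omap a [b0_map()] result.
#' @param path output file (.nii or .nii.gz).
#' @param pixel_size pixel size (m).
#' @return `path`, invisibly.
#' @export
write_b0_nifti <- function(omap, path, pixel_size) {
  RNifti::writeNifti(RNifti::asNifti(omap$hz, pixdim = rep(pixel_size * 1e3, 2)),
                     path)
  invisible(path)
}
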