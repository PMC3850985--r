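# Flow quantification: per-pixel velocity fitting, automated vessel
# segmentation, Q/A curves, upstroke detection, and the QA-method PWV fit.

#' Through-plane velocity cine from the phase data
#'
#' For each pixel and frame the phases of the velocity encodings are taken
#' relative to the flow-compensated (m1 = 0) encoding and a least-squares
#' line through the origin of phase versus `2*pi*m1` gives the velocity.
#' The reference-phase subtraction removes background (receiver, B0) phase.
#'
#' @param cine a [reconstruct_cine()] result.
#' @param m1_values reduced first moments (s/m); defaults to the cine's.
#' @return an object of class `velocity_cine`: list with `v` (m/s array,
#'   `n x n x n_frames`), `venc` (m/s), `fit_residual` (rad, same shape),
#'   `pixel_size`.
#' @export
velocity_cine <- function(cine, m1_values = cine$m1_values) {
  if (length(unique(m1_values)) < 2)
    abort_config("need at least two distinct first moments")
  ref <- which(m1_values == 0)[1]
  if (is.na(ref)) abort_config("need an m1 = 0 reference encoding")
  x <- 2 * pi * m1_values
  sxx <- sum(x^2)
  if (sxx == 0) abort_config("degenerate first-moment set")
  dims <- dim(cine$frames[[1]])
  v <- array(0, dims)
  ss <- array(0, dims)
  for (e in seq_along(m1_values)) {
    if (e == ref) next
    phi <- Arg(cine$frames[[e]] * Conj(cine$frames[[ref]]))
    v <- v + phi * x[e]
    ss <- ss + phi^2
  }
  v <- v / sxx
  resid <- sqrt(pmax(ss - v^2 * sxx, 0) / length(m1_values))
  structure(list(v = v, venc = venc_from_m1(m1_values),
                 fit_residual = resid, pixel_size = cine$pixel_size,
                 n_frames = cine$n_frames),
            class = "velocity_cine")
}

#' Segment the vessel lumen in a magnitude frame
#'
#' Otsu threshold inside a square region of interest around the seed, keep
#' the connected component containing the seed, and fill holes. Automated
#' replacement for frame-by-frame manual contouring.
#'
#' @param mag magnitude image (matrix).
#' @param seed_point pixel indices `c(row, col)` (1-based) inside the vessel.
#' @param roi_halfwidth half-width of the region of interest (pixels).
#' @param threshold absolute intensity threshold; computed at the Otsu level
#'   of the region of interest when `NULL`.
#' @return logical mask matrix of the full image size.
#' @export
segment_vessel <- function(mag, seed_point, roi_halfwidth = 16,
                           threshold = NULL) {
  n1 <- nrow(mag); n2 <- ncol(mag)
  i0 <- max(1, seed_point[1] - roi_halfwidth)
  i1 <- min(n1, seed_point[1] + roi_halfwidth)
  j0 <- max(1, seed_point[2] - roi_halfwidth)
  j1 <- min(n2, seed_point[2] + roi_halfwidth)
  roi <- mag[i0:i1, j0:j1]
  rng <- range(roi)
  if (diff(rng) <= 0) abort_segmentation("flat region of interest")
  if (is.null(threshold)) {
    sc <- (roi - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
  }
  bin <- roi > threshold
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  seed_lab <- EBImage::imageData(lab)[seed_point[1] - i0 + 1,
                                      seed_point[2] - j0 + 1]
  if (seed_lab == 0) abort_segmentation("seed pixel is not inside a component")
  comp <- EBImage::imageData(lab) == seed_lab
  comp <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
  mask <- matrix(FALSE, n1, n2)
  mask[i0:i1, j0:j1] <- comp
  mask
}

#' Segment every frame of a cine
#'
#' Two-pass automated segmentation. A first pass segments the time-mean
#' magnitude at the Otsu level of the region of interest to bootstrap the
#' vessel centroid and radius. Each frame is then thresholded at the
#' midpoint between its lumen level (mean over the core of the bootstrap
#' disk) and its tissue level (median over an outer ring): for a blurred
#' edge the midlevel crossing sits at the geometric vessel boundary
#' regardless of the inflow-driven lumen brightness, so the area waveform
#' tracks geometry rather than signal intensity.
#'
#' @param mag_frames magnitude array `n x n x n_frames` (e.g.
#'   [cine_magnitude()]).
#' @param seed_point pixel indices `c(row, col)` inside the vessel.
#' @param roi_halfwidth region-of-interest half-width (pixels).
#' @return logical array of masks, same shape.
#' @export
segment_cine <- function(mag_frames, seed_point, roi_halfwidth = 16) {
  d <- dim(mag_frames)
  nf <- d[3]
  # pass 1: bootstrap geometry from the time-mean image at the Otsu level
  avg <- apply(mag_frames, c(1, 2), mean)
  m0 <- segment_vessel(avg, seed_point, roi_halfwidth)
  idx <- which(m0, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r0 <- sqrt(sum(m0) / pi)
  ii <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
  jj <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  rr <- sqrt((ii - ctr[1])^2 + (jj - ctr[2])^2)
  core <- rr <= 0.5 * r0
  ring <- rr > 1.6 * r0 & rr <= 2.5 * r0
  out <- array(FALSE, d)
  for (f in seq_len(nf)) {
    fr <- mag_frames[, , f]
    lum <- mean(fr[core])
    tis <- median(fr[ring])
    if (lum <= tis)
      abort_segmentation("no lumen-tissue contrast at the seed")
    out[, , f] <- segment_vessel(fr, seed_point, roi_halfwidth,
                                 threshold = (lum + tis) / 2)
  }
  out
}

#' Centred moving-average smoothing
#'
#' Centred moving mean with an odd window; the window is truncated at the
#' edges. `window = 1` is the identity.
#'
#' @param x numeric vector.
#' @param window window length (odd, frames).
#' @return smoothed vector, same length.
#' @export
smooth_moving_average <- function(x, window) {
  if (window < 1 || window %% 2 == 0) abort_config("window must be odd and >= 1")
  if (window == 1) return(x)
  h <- (window - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Vessel area and volume-flow curves
#'
#' Cross-sectional area `A(t) = |mask| * pixel_area` and volume flow
#' `Q(t) = sum_mask v * pixel_area`, with optional moving-average smoothing
#' of both curves in the temporal domain. By default the flow integral uses
#' the segmentation mask dilated by one reconstruction resolution element
#' (`flow_dilation` pixels), the usual phase-contrast practice for capturing
#' the point-spread-spread partial-volume flux just outside the lumen
#' boundary; the area always comes from the undilated mask. Set
#' `flow_dilation = 0` to integrate over the segmentation mask exactly.
#'
#' @param vcine a [velocity_cine()] result.
#' @param masks logical mask array (from [segment_cine()]).
#' @param pixel_area pixel area (m^2); defaults to the cine pixel size
#'   squared.
#' @param smoothing_window moving-average window (odd number of frames;
#'   1 disables smoothing).
#' @param flow_dilation dilation radius (pixels) of the flow-integration
#'   region around the segmented lumen.
#' @return a `vessel_curves` tibble with columns `frame`, `a`, `q` (exact
#'   sums, SI units) and `a_smooth`, `q_smooth`.
#' @export
qa_curves <- function(vcine, masks, pixel_area = vcine$pixel_size^2,
                      smoothing_window = 5, flow_dilation = 2) {
  nf <- dim(masks)[3]
  brush <- if (flow_dilation > 0)
    EBImage::makeBrush(2 * flow_dilation + 1, "disc")
  a <- q <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- masks[, , f]
    fm <- if (flow_dilation > 0)
      EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1), brush)) > 0
    else m
    a[f] <- sum(m) * pixel_area
    q[f] <- sum(vcine$v[, , f][fm]) * pixel_area
  }
  out <- tibble(frame = seq_len(nf), a = a, q = q,
                a_smooth = smooth_moving_average(a, smoothing_window),
                q_smooth = smooth_moving_average(q, smoothing_window))
  structure(out, class = c("vessel_curves", class(out)),
            pixel_area = pixel_area, smoothing_window = smoothing_window)
}

#' Detect the early-systolic upstroke of the flow curve
#'
#' The onset is the last frame before the flow peak at which Q is within
#' 10 % (of the peak-to-baseline range) of the baseline; the fit range starts
#' one frame later and extends for `min(n_points_max, frames until Q reaches
#' 60 % of the peak)` frames, so that the fitted points stay in the
#' reflection-free early upstroke. Because retrospective triggering can place
#' the upstroke across the cyclic frame boundary, the search is circular by
#' default and the returned indices may wrap.
#'
#' @param q flow curve (one value per frame, cyclic).
#' @param n_points_max maximum number of fit points.
#' @param min_points minimum acceptable number of fit points.
#' @param circular treat the curve as periodic.
#' @return integer vector of frame indices (possibly wrapping); attributes
#'   `onset` and `peak`.
#' @export
detect_upstroke <- function(q, n_points_max = 8, min_points = 5,
                            circular = TRUE) {
  n <- length(q)
  qmin <- min(q); qmax <- max(q)
  if (qmax - qmin <= 0)
    stop_radialpwv("flow curve has no peak above baseline",
                   "radialpwv_resolution_error")
  p <- which.max(q)
  idx_at <- function(i) ((i - 1) %% n) + 1
  # walk back from the peak to the onset
  thr_on <- qmin + 0.1 * (qmax - qmin)
  onset <- NA_integer_
  steps <- if (circular) n - 1 else p - 1
  for (s in seq_len(steps)) {
    i <- p - s
    if (!circular && i < 1) break
    if (q[idx_at(i)] <= thr_on) { onset <- i; break }
  }
  if (is.na(onset))
    stop_radialpwv("no onset found before the flow peak",
                   "radialpwv_resolution_error")
  # unwrapped linear coordinate of the peak relative to the onset
  p_lin <- onset + ((p - onset - 1) %% n) + 1
  usable <- p_lin - onset
  if (usable < min_points)
    stop_radialpwv(sprintf(
      "only %d usable upstroke points (need >= %d): insufficient temporal resolution",
      usable, min_points), "radialpwv_resolution_error")
  thr60 <- qmin + 0.6 * (qmax - qmin)
  i60 <- onset + 1
  while (q[idx_at(i60)] < thr60 && i60 < p_lin) i60 <- i60 + 1
  n_pts <- min(n_points_max, usable, max(min_points, i60 - onset))
  idx <- idx_at(onset + seq_len(n_pts))
  structure(idx, onset = idx_at(onset), peak = p)
}

#' Fit the local pulse-wave velocity from the Q(A) relation
#'
#' Ordinary least squares of volume flow on lumen area over the early
#' upstroke: during the reflection-free early systole `PWV = dQ/dA`. With Q
#' in m^3/s and A in m^2 the slope is directly in m/s.
#'
#' @param curves a [qa_curves()] tibble.
#' @param fit_range frame indices to fit; defaults to
#'   [detect_upstroke()] on the smoothed flow curve.
#' @param use_smoothed fit the smoothed curves (recommended).
#' @param n_points_max passed to [detect_upstroke()].
#' @return an object of class `pwv_fit`: list with `pwv` (m/s),
#'   `slope_stderr`, `r_squared`, `fit_indices`, `n_fit_points`, the `lm`
#'   object, and the curves.
#' @export
fit_pwv <- function(curves, fit_range = NULL, use_smoothed = TRUE,
                    n_points_max = 8) {
  a <- if (use_smoothed) curves$a_smooth else curves$a
  q <- if (use_smoothed) curves$q_smooth else curves$q
  if (is.null(fit_range)) fit_range <- detect_upstroke(q, n_points_max)
  af <- a[fit_range]; qf <- q[fit_range]
  if (var(af) == 0) abort_config("undefined slope: area constant over the fit range")
  fit <- lm(qf ~ af)
  sm <- summary(fit)
  structure(list(pwv = unname(coef(fit)[2]),
                 slope_stderr = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 fit_indices = as.integer(fit_range),
                 n_fit_points = length(fit_range),
                 model = fit, curves = curves,
                 use_smoothed = use_smoothed),
            class = "pwv_fit")
}

#' @export
print.pwv_fit <- function(x, ...) {
  cat(sprintf("<pwv_fit> PWV = %.2f +/- %.2f m/s (R^2 = %.3f, %d upstroke points)\n",
              x$pwv, x$slope_stderr, x$r_squared, x$n_fit_points))
  invisible(x)
}

#' @export
tidy.pwv_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("(Intercept)", "area"),
         estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
         statistic = unname(sm[, 3]), p.value = unname(sm[, 4]))
}

#' @export
glance.pwv_fit <- function(x, ...) {
  tibble(pwv = x$pwv, slope_stderr = x$slope_stderr,
         r.squared = x$r_squared, n_fit_points = x$n_fit_points)
}

#' QA-plane plot of a PWV fit
#'
#' Scatter of Q against A for all frames (grey), the fitted upstroke points
#' (colour), and the fitted line whose slope is the PWV.
#'
#' @param object a [fit_pwv()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pwv_fit <- function(object, ...) {
  cv <- object$curves
  a <- (if (object$use_smoothed) cv$a_smooth else cv$a) * 1e6   # mm^2
  q <- (if (object$use_smoothed) cv$q_smooth else cv$q) * 1e6   # cm^3/s
  df <- tibble(a = a, q = q,
               fitted = seq_along(a) %in% object$fit_indices)
  co <- coef(object$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$q)) +
    ggplot2::geom_path(colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fitted), size = 1.2) +
    ggplot2::geom_abline(slope = co[2], intercept = co[1] * 1e6,
                         colour = "red", linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c("grey40", "red"), guide = "none") +
    ggplot2::labs(x = expression(A ~ (mm^2)), y = expression(Q ~ (cm^3/s)),
                  subtitle = sprintf("PWV = %.2f m/s", object$pwv))
  }

#' Q(t)/A(t) curve plot
#'
#' @param curves a [qa_curves()] tibble.
#' @return a ggplot object.
#' @export
plot_qa_curves <- function(curves) {
  df <- tibble(frame = rep(curves$frame, 2),
               value = c(curves$q_smooth * 1e6, curves$a_smooth * 1e6),
               series = rep(c("Q (cm^3/s)", "A (mm^2)"),
                            each = nrow(curves)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "cine frame", y = NULL)
}
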