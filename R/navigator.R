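# Navigator extraction from the k-space centre and its filtering:
# Butterworth low-pass (zero-phase) and Gaussian-window high-pass.

#' Navigator filter specification
#'
#' Band edges of the Butterworth low-pass (pass band up to 10-13 Hz, stop
#' band from 15-20 Hz; defaults use the widest stated transition, 10 to
#' 20 Hz, which keeps the filter order moderate and limits ringing between
#' heartbeats; 3 dB ripple, 40 dB attenuation) and the width of the Gaussian
#' high-pass window `w(f) = 1 - exp(-(f/sigma)^2)` used to remove the
#' respiratory baseline.
#'
#' @param pass_band upper edge of the pass band (Hz).
#' @param stop_band lower edge of the stop band (Hz).
#' @param sigma Gaussian high-pass width (Hz), typically 4-8 Hz.
#' @param pass_ripple maximum pass-band ripple (dB).
#' @param stop_atten minimum stop-band attenuation (dB).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(pass_band = 10, stop_band = 20, sigma = 6,
                        pass_ripple = 3, stop_atten = 40) {
  if (!(pass_band < stop_band)) abort_config("pass_band must be below stop_band")
  if (sigma <= 0) abort_config("sigma must be positive")
  structure(list(pass_band = pass_band, stop_band = stop_band, sigma = sigma,
                 pass_ripple = pass_ripple, stop_atten = stop_atten),
            class = "filter_spec")
}

#' Extract navigator signals from the k-space centre
#'
#' Takes the echo (k-space centre) sample of every projection of one
#' velocity encoding and returns the real part, imaginary part and magnitude
#' time series. The first `floor(1.5 s / TR)` projections are discarded
#' because the signal is still approaching steady state (500 projections at
#' TR = 3 ms).
#'
#' @param projset a [simulate_acquisition()] result or compatible list with
#'   `kspace`, `acq`, `proj_times`.
#' @param encoding which velocity encoding to use (1-based).
#' @param discard_time leading data to exclude (s).
#' @return a `navigator_set` tibble with columns `projection`, `time`,
#'   `real`, `imaginary`, `magnitude`; attributes `tr` and `n_discarded`.
#' @export
extract_navigator <- function(projset, encoding = 1, discard_time = 1.5) {
  acq <- projset$acq
  if (acq$idx_echo + 1 > acq$n_readout)
    abort_config("echo sample missing from the readout")
  center <- projset$kspace[[encoding]][acq$idx_echo + 1, ]
  nd <- min(floor(discard_time / acq$tr), length(center) - 1)
  keep <- (nd + 1):length(center)
  out <- tibble(projection = keep,
                time = projset$proj_times[keep, encoding],
                real = Re(center[keep]),
                imaginary = Im(center[keep]),
                magnitude = Mod(center[keep]))
  structure(out, class = c("navigator_set", class(out)),
            tr = acq$tr, n_discarded = nd, encoding = encoding)
}

# one-sided band power in [f1, f2] Hz of a detrended series sampled at fs
band_power <- function(x, fs, f1, f2) {
  n <- length(x)
  x <- x - mean(x)
  tt <- seq_len(n)
  x <- x - coef(lm(x ~ tt))[2] * (tt - mean(tt))    # linear detrend
  p <- Mod(fft(x))^2 / n
  f <- (0:(n - 1)) / n * fs
  sum(p[f >= f1 & f <= f2 & f <= fs / 2])
}

#' Select the navigator channel with the strongest cardiac modulation
#'
#' Compares the band power in the cardiac band (5-15 Hz by default) of the
#' magnitude, real and imaginary k-space-centre channels after detrending and
#' returns the strongest as the working navigator. Ties are broken with the
#' precedence magnitude > real > imaginary.
#'
#' @param navset a [extract_navigator()] result.
#' @param band cardiac frequency band (Hz).
#' @return a `navigator` tibble with columns `projection`, `time`, `value`;
#'   attributes `channel`, `tr`, `n_discarded`.
#' @export
select_channel <- function(navset, band = c(5, 15)) {
  tr <- attr(navset, "tr")
  chans <- c("magnitude", "real", "imaginary")
  pw <- vapply(chans, function(ch)
    band_power(navset[[ch]], 1 / tr, band[1], band[2]), numeric(1))
  if (all(vapply(chans, function(ch) all(navset[[ch]] == 0), logical(1))))
    abort_gating("all navigator channels are zero")
  ch <- chans[which.max(pw)]    # which.max takes the first maximum: tie-break
  out <- tibble(projection = navset$projection, time = navset$time,
                value = navset[[ch]])
  structure(out, class = c("navigator", class(out)),
            channel = ch, tr = tr,
            n_discarded = attr(navset, "n_discarded"),
            band_power = pw)
}

# Minimal Butterworth order meeting (pass_ripple dB at wp, stop_atten dB at
# ws) and the matching cutoff; classic closed forms.
butterworth_design <- function(spec) {
  wp <- spec$pass_band; ws <- spec$stop_band
  if (ws <= wp) abort_config("filter specification not meetable")
  num <- 10^(spec$stop_atten / 10) - 1
  den <- 10^(spec$pass_ripple / 10) - 1
  n <- ceiling(log10(num / den) / (2 * log10(ws / wp)))
  fc <- wp / den^(1 / (2 * n))
  list(order = n, cutoff = fc)
}

# zero-phase frequency-domain application: multiply the spectrum by the
# squared Butterworth magnitude (identical to forward-backward filtering)
butter_lp_vec <- function(x, fs, spec) {
  d <- butterworth_design(spec)
  n <- length(x)
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)                       # |f| on the periodic axis
  h2 <- 1 / (1 + (f / d$cutoff)^(2 * d$order))
  Re(fft(fft(x) * h2, inverse = TRUE)) / n
}

gauss_hp_vec <- function(x, fs, sigma) {
  n <- length(x)
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)
  w <- 1 - exp(-(f / sigma)^2)
  Re(fft(fft(x) * w, inverse = TRUE)) / n
}

#' Butterworth low-pass filter a navigator (zero phase)
#'
#' Applies the minimal-order Butterworth low-pass meeting the ripple /
#' attenuation specification at the band edges, as a zero-phase (forward-
#' backward) filter so trigger timing is preserved.
#'
#' @param nav a `navigator` tibble (from [select_channel()]).
#' @param spec a [filter_spec()].
#' @return the navigator with `value` replaced by the filtered signal.
#' @export
butterworth_lowpass <- function(nav, spec = filter_spec()) {
  fs <- 1 / attr(nav, "tr")
  if (fs <= 2 * spec$stop_band)
    abort_config("sampling rate must exceed twice the stop-band edge")
  nav$value <- butter_lp_vec(nav$value, fs, spec)
  nav
}

#' Gaussian high-pass filter a navigator
#'
#' Multiplies the spectrum by `w(f) = 1 - exp(-(f/sigma)^2)`, removing the
#' DC component and the low-frequency respiratory baseline.
#'
#' @param nav a `navigator` tibble.
#' @param sigma window width (Hz).
#' @return the navigator with `value` replaced by the filtered signal.
#' @export
gaussian_highpass <- function(nav, sigma = 6) {
  if (sigma <= 0) abort_config("sigma must be positive")
  nav$value <- gauss_hp_vec(nav$value, 1 / attr(nav, "tr"), sigma)
  nav
}

#' Full navigator filter chain
#'
#' Butterworth low-pass followed by Gaussian high-pass. The result keeps the
#' raw signal (`raw`), the low-passed signal (`lowpass`), the final filtered
#' signal (`value`) and the low-frequency residual removed by the high-pass
#' (`lowfreq`, used for respiratory gating).
#'
#' @param nav a `navigator` tibble.
#' @param spec a [filter_spec()].
#' @return the navigator tibble with the added columns.
#' @export
filter_navigator <- function(nav, spec = filter_spec()) {
  fs <- 1 / attr(nav, "tr")
  raw <- nav$value
  lp <- butter_lp_vec(raw, fs, spec)
  hp <- gauss_hp_vec(lp, fs, spec$sigma)
  nav$raw <- raw
  nav$lowpass <- lp
  nav$value <- hp
  nav$lowfreq <- lp - hp
  nav
}

#' Navigator diagnostic plot
#'
#' Raw and filtered navigator over time, with detected triggers overlaid if
#' supplied.
#'
#' @param nav a filtered navigator (from [filter_navigator()]).
#' @param triggers optional [detect_triggers()] result.
#' @param window time window (s) to display.
#' @return a ggplot object.
#' @export
plot_navigator <- function(nav, triggers = NULL, window = c(0, 5)) {
  df <- nav[nav$time >= window[1] & nav$time <= window[2], ]
  long <- tidyr::pivot_longer(
    df[, c("time", if ("raw" %in% names(df)) "raw", "value")],
    -"time", names_to = "series", values_to = "y")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "navigator (a.u.)")
  if (!is.null(triggers)) {
    tt <- triggers$time[triggers$time >= window[1] & triggers$time <= window[2]]
    p <- p + ggplot2::geom_vline(xintercept = tt, colour = "red",
                                 linetype = 3, linewidth = 0.2)
  }
  p
}
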