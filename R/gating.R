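# Trigger detection on the filtered navigator, relative cardiac-phase
# assignment with respiratory gate-out, and sliding-window frame selection.

#' Detect cardiac trigger points
#'
#' The filtered navigator is linearly interpolated to `TR / interpolation_factor`,
#' local maxima are found subject to a refractory period, and for each
#' maximum the trigger is the first interpolated sample in that cycle whose
#' value rises above 90 % of the local maximum (the first up-crossing
#' preceding the peak).
#'
#' @param nav a filtered `navigator` tibble ([filter_navigator()]).
#' @param interpolation_factor temporal oversampling of the navigator grid.
#' @param threshold_frac trigger threshold as a fraction of each local
#'   maximum.
#' @param refractory minimum spacing between local maxima (s); peaks closer
#'   than this keep only the larger one.
#' @return a `trigger_set` tibble with column `time` (s); attributes
#'   `intervals` (successive differences) and `interpolation_factor`.
#' @export
detect_triggers <- function(nav, interpolation_factor = 10,
                            threshold_frac = 0.9, refractory = 0.05) {
  tr <- attr(nav, "tr")
  tt <- seq(nav$time[1], nav$time[nrow(nav)], by = tr / interpolation_factor)
  x <- approx(nav$time, nav$value, xout = tt)$y
  n <- length(x)
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  peaks <- which(is_max & x > 0)   # trigger lobes are positive after filtering
  if (!length(peaks)) abort_gating("no local maxima in the navigator signal")
  # refractory suppression, larger peaks win
  ord <- peaks[order(x[peaks], decreasing = TRUE)]
  kept_idx <- integer(0)
  kept_t <- numeric(0)
  for (p in ord) {
    if (!length(kept_t) || min(abs(tt[p] - kept_t)) >= refractory) {
      kept_t <- c(kept_t, tt[p])
      kept_idx <- c(kept_idx, p)
    }
  }
  peaks <- sort(kept_idx)
  # first up-crossing of 0.9 * peak within each cycle (from preceding trough)
  trig <- numeric(length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    lo <- if (i == 1) 1 else peaks[i - 1]
    seg <- lo:p
    trough <- seg[which.min(x[seg])]
    thr <- threshold_frac * x[p]
    above <- which(x[trough:p] >= thr)
    trig[i] <- tt[trough + above[1] - 1]
  }
  out <- tibble(time = trig)
  structure(out, class = c("trigger_set", class(out)),
            intervals = diff(trig),
            interpolation_factor = interpolation_factor)
}

#' @export
glance.trigger_set <- function(x, ...) {
  iv <- attr(x, "intervals")
  tibble(n_triggers = nrow(x), mean_rr = mean(iv), sd_rr = sd(iv))
}

# Respiratory intervals from the low-frequency navigator residual: flag
# samples deviating from a running median by more than k_resp * MAD, dilated
# by a guard margin. Returns the flagged navigator times.
detect_resp_times <- function(nav, k_resp = 4, runmed_span = 1.2) {
  if (!"lowfreq" %in% names(nav)) return(numeric(0))
  tr <- attr(nav, "tr")
  k <- floor(runmed_span / tr / 2) * 2 + 1
  k <- min(k, floor((nrow(nav) - 1) / 2) * 2 + 1)
  r <- nav$lowfreq - runmed(nav$lowfreq, k)
  m <- mad(r)
  if (m == 0) return(numeric(0))
  nav$time[abs(r) > k_resp * m]
}

#' Assign relative cardiac phase and gate out respiration
#'
#' Each projection time between triggers `T_i` and `T_{i+1}` receives the
#' relative heart-cycle position `(t - T_i)/(T_{i+1} - T_i)` in `[0, 1]`.
#' Projections before the first or after the last trigger, and projections
#' within a detected respiratory interval (low-frequency navigator residual
#' beyond `k_resp` MADs of its running median, dilated by `guard` seconds),
#' are gated out with position -1.
#'
#' @param nav a filtered `navigator` tibble (supplies the respiratory
#'   residual; pass `NULL` to skip respiratory gating).
#' @param triggers a [detect_triggers()] result (needs >= 2 triggers).
#' @param times projection times to map (s); defaults to the navigator times.
#' @param projections projection indices matching `times`.
#' @param k_resp MAD multiplier of the respiratory detector.
#' @param guard dilation of detected respiratory samples (s).
#' @return a `cardiac_phase_map` tibble with columns `projection`, `time`,
#'   `rel_position`; attributes `triggers` and `resp_times`.
#' @export
assign_cardiac_phase <- function(nav, triggers, times = NULL,
                                 projections = NULL, k_resp = 4,
                                 guard = 0.03) {
  if (nrow(triggers) < 2) abort_gating("need at least two triggers")
  if (is.null(times)) times <- nav$time
  if (is.null(projections))
    projections <- if (!is.null(nav) && length(times) == nrow(nav))
      nav$projection else seq_along(times)
  tg <- triggers$time
  i <- findInterval(times, tg)
  rel <- rep(-1, length(times))
  ok <- i >= 1 & i < length(tg)
  rel[ok] <- (times[ok] - tg[i[ok]]) / (tg[i[ok] + 1] - tg[i[ok]])
  rel[times %in% tg[length(tg)]] <- 0   # exactly on the final trigger
  resp_t <- if (is.null(nav)) numeric(0) else detect_resp_times(nav, k_resp)
  if (length(resp_t)) {
    rs <- sort(resp_t)
    near_resp <- function(x) {
      j <- findInterval(x, rs)
      d_prev <- ifelse(j >= 1, x - rs[pmax(j, 1)], Inf)
      d_next <- ifelse(j < length(rs), rs[pmin(j + 1, length(rs))] - x, Inf)
      pmin(d_prev, d_next) <= guard
    }
    rel[near_resp(times)] <- -1
    # Triggers derived from breath-corrupted navigator segments are
    # unreliable, so whole cycles bounded by such a trigger are gated out
    # as well (their relative positions would be wrong, not just noisy).
    bad_tg <- which(near_resp(tg))
    if (length(bad_tg)) {
      bad_cycle <- unique(c(bad_tg - 1, bad_tg))
      rel[i %in% bad_cycle[bad_cycle >= 1]] <- -1
    }
  }
  out <- tibble(projection = projections, time = times, rel_position = rel)
  structure(out, class = c("cardiac_phase_map", class(out)),
            triggers = tg, resp_times = resp_t)
}

# Circular position (in relative-phase units) of the navigator event: the
# peak of the phase-locked |deviation-from-baseline| profile of the raw
# navigator. Used to orient the trigger feature.
event_profile_peak <- function(raw, rel, n_bins = 50) {
  ok <- rel >= 0
  bin <- pmin(floor(rel[ok] * n_bins), n_bins - 1)
  pr <- rep(NA_real_, n_bins)
  mm <- tapply(raw[ok], bin, mean)
  pr[as.integer(names(mm)) + 1] <- mm
  dev <- abs(pr - median(pr, na.rm = TRUE))
  dev[is.na(dev)] <- 0
  sm <- stats::filter(rep(dev, 3), rep(1 / 3, 3), sides = 2)[(n_bins + 1):(2 * n_bins)]
  (which.max(sm) - 0.5) / n_bins
}

#' Orient the navigator so the trigger precedes the flow event
#'
#' The filtered navigator is nearly sinusoidal, so trigger detection locks
#' stably to either its positive or its negative lobes; which lobe marks the
#' systolic flow event depends on the sign of the k-centre modulation (and
#' hence on the velocity encoding and the off-resonant phase of the blood
#' pool). This function detects triggers, assigns phases, and checks where
#' the phase-locked raw-navigator deviation peaks: just after the trigger
#' (upright) or around mid-cycle (inverted). In the latter case the filtered
#' signal is negated and triggers are re-detected, which shifts the trigger
#' feature by half a cycle and makes the trigger sets of all velocity
#' encodings lock to the same physical event.
#'
#' @param nav a filtered `navigator` ([filter_navigator()]).
#' @param ... passed to [detect_triggers()].
#' @return list with the (possibly negated) `nav`, the `triggers`, the
#'   navigator-level `phase_map`, and `flipped` (logical).
#' @export
orient_triggers <- function(nav, ...) {
  tg <- detect_triggers(nav, ...)
  pm <- assign_cardiac_phase(nav, tg)
  pk <- event_profile_peak(nav$raw, pm$rel_position)
  flipped <- pk > 0.3 && pk < 0.8
  if (flipped) {
    nav$value <- -nav$value
    tg <- detect_triggers(nav, ...)
    pm <- assign_cardiac_phase(nav, tg)
  }
  list(nav = nav, triggers = tg, phase_map = pm, flipped = flipped)
}

#' Sliding-window frame selection
#'
#' Divides the heart cycle into `n_frames` equidistant target phases
#' `f / n_frames` and assigns a projection to frame `f` if its temporal
#' distance from the target phase, measured in absolute time within its own
#' cardiac cycle (`(rel - f/n_frames) * RR_i`), is at most
#' `window_halfwidth`. The windows slide, so one projection may join several
#' frames; gated-out projections join none.
#'
#' @param phasemap a [assign_cardiac_phase()] result.
#' @param n_frames number of cine frames per cycle.
#' @param window_halfwidth half-width of the selection window (s).
#' @return a `frame_selection` tibble with columns `frame` (1-based),
#'   `projection`, `time`, `rel_position`; attributes `n_frames`,
#'   `window_halfwidth`, `empty_frames`.
#' @export
select_frames <- function(phasemap, n_frames = 100, window_halfwidth = 0.5e-3) {
  if (n_frames < 1) abort_config("n_frames must be >= 1")
  tg <- attr(phasemap, "triggers")
  keep <- phasemap$rel_position >= 0
  t <- phasemap$time[keep]
  rel <- phasemap$rel_position[keep]
  proj <- phasemap$projection[keep]
  i <- pmin(pmax(findInterval(t, tg), 1), length(tg) - 1)
  rr <- tg[i + 1] - tg[i]
  dw <- window_halfwidth / rr                      # phase half-width
  f_lo <- pmax(ceiling((rel - dw) * n_frames), 0)
  f_hi <- pmin(floor((rel + dw) * n_frames), n_frames - 1)
  nrep <- pmax(f_hi - f_lo + 1, 0)
  sel <- nrep > 0
  frames <- unlist(mapply(seq, f_lo[sel], f_hi[sel], SIMPLIFY = FALSE))
  out <- tibble(frame = frames + 1L,
                projection = rep(proj[sel], nrep[sel]),
                time = rep(t[sel], nrep[sel]),
                rel_position = rep(rel[sel], nrep[sel]))
  out <- out[order(out$frame, out$projection), ]
  empty <- setdiff(seq_len(n_frames), unique(out$frame))
  if (length(empty))
    warning(sprintf("%d frames have no projections", length(empty)))
  structure(out, class = c("frame_selection", class(out)),
            n_frames = n_frames, window_halfwidth = window_halfwidth,
            empty_frames = empty, triggers = tg)
}

#' @export
glance.frame_selection <- function(x, ...) {
  counts <- tabulate(x$frame, nbins = attr(x, "n_frames"))
  # temporal blur: mean within-frame s.d. of the members' absolute offsets
  tg <- attr(x, "triggers")
  i <- pmin(pmax(findInterval(x$time, tg), 1), length(tg) - 1)
  rr <- tg[i + 1] - tg[i]
  off <- (x$rel_position - (x$frame - 1) / attr(x, "n_frames")) * rr
  blur <- mean(tapply(off, x$frame, sd), na.rm = TRUE)
  tibble(n_frames = attr(x, "n_frames"),
         mean_members = mean(counts), min_members = min(counts),
         temporal_blur_s = blur)
}
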