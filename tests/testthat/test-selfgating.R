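test_that("navigator extraction discards the steady-state transient", {
  sim <- simulate_acquisition(quiet_phantom(), small_acq(n_proj = 600), seed = 1)
  nav <- extract_navigator(sim, 1)
  expect_equal(attr(nav, "n_discarded"), 500)   # 1.5 s at TR = 3 ms
  expect_equal(nrow(nav), 100)
  expect_named(nav, c("projection", "time", "real", "imaginary", "magnitude"))
})

test_that("a static phantom gives a flat magnitude navigator", {
  sim <- simulate_acquisition(static_phantom(noise_sd = 0),
                              small_acq(n_proj = 560), seed = 1)
  nav <- extract_navigator(sim, 1)
  expect_lt(sd(nav$magnitude) / mean(nav$magnitude), 1e-8)
})

test_that("the cardiac modulation peaks at the heart rate", {
  sim <- simulate_acquisition(quiet_phantom(), small_acq(n_proj = 3000), seed = 2)
  nav <- select_channel(extract_navigator(sim, 1))
  x <- nav$value - mean(nav$value)
  p <- Mod(fft(x))^2
  f <- (0:(length(x) - 1)) / length(x) / 3e-3
  band <- f > 4 & f < 20
  expect_equal(f[band][which.max(p[band])], 1 / 0.1072, tolerance = 0.05)
})

test_that("channel selection maximizes cardiac band power with tie-breaks", {
  tt <- (0:999) * 3e-3
  base <- tibble::tibble(projection = 1:1000, time = tt,
                         real = rep(0, 1000), imaginary = rep(0, 1000),
                         magnitude = sin(2 * pi * 8 * tt))
  navset <- structure(base, class = c("navigator_set", class(base)),
                      tr = 3e-3, n_discarded = 0L)
  expect_equal(attr(select_channel(navset), "channel"), "magnitude")
  # modulation on the imaginary channel only
  navset$magnitude <- rep(0, 1000)
  navset$imaginary <- sin(2 * pi * 8 * tt)
  expect_equal(attr(select_channel(navset), "channel"), "imaginary")
  # exact tie: precedence magnitude > real > imaginary
  navset$magnitude <- navset$imaginary
  navset$real <- navset$imaginary
  expect_equal(attr(select_channel(navset), "channel"), "magnitude")
  navset$magnitude <- navset$real <- navset$imaginary <- rep(0, 1000)
  expect_error(select_channel(navset), class = "radialpwv_gating_error")
})

test_that("Butterworth low-pass meets its band specification", {
  spec <- filter_spec(pass_band = 13, stop_band = 15, stop_atten = 40)
  tt <- (0:999) * 3e-3                       # 3 s: integer cycles for 9/25 Hz
  dc <- mk_nav(rep(2.5, 1000))
  expect_equal(butterworth_lowpass(dc, spec)$value, rep(2.5, 1000),
               tolerance = 1e-9)
  s25 <- mk_nav(sin(2 * pi * 25 * tt))
  out25 <- butterworth_lowpass(s25, spec)$value
  expect_lte(sqrt(mean(out25^2)), 10^(-40 / 20) * sqrt(0.5))
  s9 <- mk_nav(sin(2 * pi * 9 * tt))
  out9 <- butterworth_lowpass(s9, spec)$value
  expect_gte(sqrt(mean(out9^2)), 0.7 * sqrt(0.5))
  expect_config_error(filter_spec(pass_band = 15, stop_band = 13))
})

test_that("Gaussian high-pass has the analytic window gains", {
  tt <- (0:999) * 3e-3
  dc <- gaussian_highpass(mk_nav(rep(1, 1000)), sigma = 4)
  expect_lt(max(abs(dc$value)), 1e-12)       # w(0) = 0
  s4 <- gaussian_highpass(mk_nav(sin(2 * pi * 4 * tt)), sigma = 4)
  expect_equal(sqrt(mean(s4$value^2)) / sqrt(0.5), 1 - exp(-1), tolerance = 1e-6)
  s8 <- gaussian_highpass(mk_nav(sin(2 * pi * 8 * tt)), sigma = 4)
  expect_equal(sqrt(mean(s8$value^2)) / sqrt(0.5), 1 - exp(-4), tolerance = 1e-6)
})

test_that("the filter chain is linear", {
  set.seed(4)
  x <- rnorm(600); y <- rnorm(600)
  f <- function(v) filter_navigator(mk_nav(v))$value
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
})

test_that("triggers on a pure sinusoid are evenly spaced", {
  tt <- seq(0, 48, by = 3e-3)
  nav <- mk_nav(sin(2 * pi * tt / 0.1072))
  nav$raw <- nav$value
  tg <- detect_triggers(nav)
  iv <- attr(tg, "intervals")
  expect_equal(nrow(tg), floor(48 / 0.1072), tolerance = 0.01)
  expect_lt(mean(abs(iv - 0.1072)), 3e-4)    # interpolation-grid resolution
  expect_lt(max(abs(iv - 0.1072)), 7e-4)     # worst case: two grid steps
  flat <- mk_nav(rep(0, 1000))
  expect_error(detect_triggers(flat), class = "radialpwv_gating_error")
})

test_that("detected triggers track the simulated beats", {
  sim <- simulate_acquisition(quiet_phantom(), small_acq(n_proj = 3000), seed = 3)
  nav <- filter_navigator(select_channel(extract_navigator(sim, 1)))
  ot <- orient_triggers(nav)
  tg <- ot$triggers
  gt <- sim$ground_truth$trigger_times
  gte <- gt[gt >= nav$time[1] & gt <= max(nav$time)]
  expect_lte(abs(nrow(tg) - length(gte)), 1)
  m <- sapply(tg$time, function(t) which.min(abs(t - gte)))
  ok <- diff(m) == 1
  err <- attr(tg, "intervals")[ok] - diff(gte)[m[-length(m)][ok]]
  # structural floor of a <= 13 Hz navigator under 4.1 ms RR variability
  expect_lt(mean(abs(err)), 3e-3)
})

test_that("phase assignment is piecewise linear with gate-out", {
  tg <- mk_triggers(c(1, 1.1, 1.2, 1.35))
  times <- c(0.95, 1, 1.05, 1.15, 1.2, 1.275, 1.4)
  pm <- assign_cardiac_phase(NULL, tg, times = times)
  expect_equal(pm$rel_position, c(-1, 0, 0.5, 0.5, 0, 0.5, -1))
  # monotone within one interval
  ts <- seq(1.0, 1.0999, by = 1e-3)
  pm2 <- assign_cardiac_phase(NULL, tg, times = ts)
  expect_true(all(diff(pm2$rel_position) >= 0))
  expect_error(assign_cardiac_phase(NULL, mk_triggers(1)),
               class = "radialpwv_gating_error")
})

test_that("respiratory intervals are gated out with high sensitivity", {
  sim <- simulate_acquisition(phantom_config(b0_peak = 0),
                              small_acq(n_proj = 3000), seed = 5)
  nav <- filter_navigator(select_channel(extract_navigator(sim, 1)))
  ot <- orient_triggers(nav)
  pm <- assign_cardiac_phase(ot$nav, ot$triggers,
                             times = sim$proj_times[, 1],
                             projections = seq_len(3000))
  gtp <- sim$ground_truth$per_projection
  g1 <- gtp[gtp$encoding == 1, ]
  tgt <- ot$triggers$time
  inw <- g1$time >= tgt[1] & g1$time <= tgt[length(tgt)]
  sens <- mean(pm$rel_position[g1$in_resp & inw] == -1)
  expect_gte(sens, 0.9)
  # a reasonable share of quiet data must survive
  expect_gte(mean(pm$rel_position[!g1$in_resp & inw] >= 0), 0.5)
})

test_that("sliding-window frame selection matches a brute-force count", {
  tg <- mk_triggers(seq(1, 9, by = 0.1072))
  times <- seq(1.01, 8.9, by = 3e-3)
  pm <- assign_cardiac_phase(NULL, tg, times = times)
  fs <- suppressWarnings(select_frames(pm, n_frames = 40,
                                       window_halfwidth = 0.5e-3))
  # independent O(n * frames) membership count
  counts <- integer(40)
  tgv <- tg$time
  for (i in seq_along(times)) {
    r <- pm$rel_position[i]
    if (r < 0) next
    k <- findInterval(times[i], tgv)
    rr <- tgv[k + 1] - tgv[k]
    for (f in 0:39)
      if (abs((r - f / 40) * rr) <= 0.5e-3) counts[f + 1] <- counts[f + 1] + 1
  }
  expect_equal(tabulate(fs$frame, 40), counts)
  # zero window selects a subset of any positive window
  fs0 <- suppressWarnings(select_frames(pm, 40, 0))
  key <- function(x) paste(x$frame, x$projection)
  expect_true(all(key(fs0) %in% key(fs)))
})

test_that("frame membership is stable under a whole-period time shift", {
  sim <- simulate_acquisition(quiet_phantom(), small_acq(n_proj = 3000), seed = 6)
  nav <- filter_navigator(select_channel(extract_navigator(sim, 1)))
  ot <- orient_triggers(nav)
  pm <- assign_cardiac_phase(ot$nav, ot$triggers)
  fs1 <- suppressWarnings(select_frames(pm, 50))
  rr <- median(attr(ot$triggers, "intervals"))
  pm2 <- pm
  pm2$time <- pm$time + rr
  attr(pm2, "triggers") <- attr(pm, "triggers")
  keep <- pm2$time <= max(attr(pm, "triggers"))
  pm2 <- pm2[keep, ]
  attr(pm2, "triggers") <- attr(pm, "triggers")
  class(pm2) <- class(pm)
  fs2 <- suppressWarnings(select_frames(pm2, 50))
  c1 <- mean(tabulate(fs1$frame, 50))
  c2 <- mean(tabulate(fs2$frame, 50)) * nrow(pm) / sum(keep)
  expect_lt(abs(c1 - c2) / c1, 0.05)
})

test_that("average members per frame follow the window/TR ratio", {
  # constant RR 107.2 ms over 24 s, no gating: expect ~ (1 ms / 3 ms) per beat
  tg <- mk_triggers(seq(0, 24, by = 0.1072))
  times <- seq(0.001, 23.9, by = 3e-3)
  pm <- assign_cardiac_phase(NULL, tg, times = times)
  fs <- suppressWarnings(select_frames(pm, 100, 0.5e-3))
  beats <- length(tg$time) - 1
  expect_equal(mean(tabulate(fs$frame, 100)), beats / 3, tolerance = 0.1)
})
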