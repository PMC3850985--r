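# helper: build a minimal cine_stack with constant per-encoding phases
mk_cine <- function(phases, mag = 1, n = 8, nf = 2, m1 = c(0, 0.3, -0.3)) {
  frames <- lapply(phases, function(p)
    array(mag * exp(1i * p), c(n, n, nf)))
  structure(list(frames = frames, pixel_size = 24e-3 / 256, n_frames = nf,
                 matrix = n, zero_fill_matrix = n, m1_values = m1,
                 flagged_frames = integer(0)),
            class = "cine_stack")
}

test_that("velocity mapping fits phase against the first moments", {
  vc <- velocity_cine(mk_cine(c(0, 0.6 * pi, -0.6 * pi)))
  expect_equal(vc$v[1, 1, 1], 1.0, tolerance = 1e-12)
  expect_equal(vc$venc, 1 / 0.6)
  expect_equal(round(vc$venc, 1), 1.7)
  expect_equal(max(abs(velocity_cine(mk_cine(c(0, 0, 0)))$v)), 0)
  # negating the moments negates the velocity pixelwise
  vneg <- velocity_cine(mk_cine(c(0, 0.6 * pi, -0.6 * pi)),
                        m1_values = c(0, -0.3, 0.3))
  expect_equal(vneg$v, -vc$v)
  expect_config_error(velocity_cine(mk_cine(c(0, 0, 0)),
                                    m1_values = c(0, 0, 0)))
})

test_that("vessel segmentation recovers a known lumen area", {
  set.seed(31)
  n <- 96
  cov <- radialpwv:::disk_coverage(0.02, -0.01, 0.05, n)    # FOV units
  img <- 1 + cov + matrix(rnorm(n * n, 0, 0.05), n, n)      # 2:1 contrast
  seed_pt <- c(n / 2 + 1 + round(0.02 * n), n / 2 + 1 - round(0.01 * n))
  mask <- segment_vessel(img, seed_pt, roi_halfwidth = 12)
  expect_equal(sum(mask), sum(cov), tolerance = 0.05)
  # a mask of 83 pixels at the zero-filled pitch is 0.7294 mm^2
  expect_equal(83 * (93.75e-6)^2 * 1e6, 0.7294, tolerance = 1e-3)
  flat <- matrix(1, n, n)
  expect_error(segment_vessel(flat, c(10, 10), 8),
               class = "radialpwv_segmentation_error")
})

test_that("Q/A curves are exact sums over the masks", {
  n <- 32; nf <- 3
  v <- array(0, c(n, n, nf))
  masks <- array(FALSE, c(n, n, nf))
  masks[5:13, 5:13, ] <- TRUE                 # 81 pixels
  v[5:13, 5:13, ] <- 0.5
  vc <- structure(list(v = v, venc = 1 / 0.6, pixel_size = 93.75e-6,
                       n_frames = nf), class = "velocity_cine")
  cv <- qa_curves(vc, masks, smoothing_window = 1, flow_dilation = 0)
  expect_equal(cv$a, rep(81 * (93.75e-6)^2, nf))
  expect_equal(cv$q, 0.5 * cv$a)               # uniform v: Q = v * A
  # uniform 0.5 m/s over 0.73 mm^2 is 0.365 cm^3/s
  expect_equal(0.5 * 0.73e-6 * 1e6, 0.365)
  # zero-velocity cine: Q = 0, A > 0
  vc$v[] <- 0
  cv0 <- qa_curves(vc, masks, smoothing_window = 1, flow_dilation = 0)
  expect_equal(cv0$q, rep(0, nf))
  expect_true(all(cv0$a > 0))
  # random fields: exact agreement with a brute-force sum
  set.seed(32)
  vc$v <- array(rnorm(n * n * nf), c(n, n, nf))
  cvr <- qa_curves(vc, masks, smoothing_window = 1, flow_dilation = 0)
  manual <- sapply(1:nf, function(f) sum(vc$v[, , f][masks[, , f]]))
  expect_equal(cvr$q, manual * (93.75e-6)^2)
})

test_that("moving-average smoothing behaves analytically", {
  expect_equal(smooth_moving_average(rep(3, 10), 5), rep(3, 10))
  x <- rnorm(20)
  expect_equal(smooth_moving_average(x, 1), x)
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- smooth_moving_average(imp, 5)
  expect_equal(sm[9:13], rep(0.2, 5))
  expect_equal(sum(sm[c(1:8, 14:21)]), 0)
  expect_config_error(smooth_moving_average(x, 4))
  # mean preserved up to edge truncation
  y <- sin(2 * pi * (0:99) / 25)
  expect_lt(abs(mean(smooth_moving_average(y, 5)) - mean(y)), 2 * 2 / 100)
})

test_that("upstroke detection selects the early rising flank", {
  q <- c(rep(0, 20), (1:8) / 8, rev((0:7) / 8) * 0.9, rep(0, 14))
  idx <- detect_upstroke(q, circular = FALSE)
  # onset frame 20 (last at baseline), 60 % reached at frame 25: five points
  expect_equal(as.integer(idx), 21:25)
  expect_equal(attr(idx, "peak"), 28)
  expect_error(detect_upstroke(rep(1, 30)), class = "radialpwv_resolution_error")
  # circular handling: the same curve rotated across the frame boundary
  rot <- c(q[25:50], q[1:24])
  idx2 <- detect_upstroke(rot)
  expect_equal(q[as.integer(idx)], rot[as.integer(idx2)])
  # too coarse a sampling of the upstroke errors out
  q2 <- c(rep(0, 10), 0.5, 1, 0.5, rep(0, 10))
  expect_error(detect_upstroke(q2), class = "radialpwv_resolution_error")
})

test_that("the QA fit recovers an exact linear relation", {
  a <- seq(0.61e-6, 0.73e-6, length.out = 8)
  q <- 2.3 * (a - 0.61e-6)
  cv <- tibble::tibble(frame = 1:8, a = a, q = q, a_smooth = a, q_smooth = q)
  class(cv) <- c("vessel_curves", class(cv))
  fit <- fit_pwv(cv, fit_range = 1:8)
  expect_equal(fit$pwv, 2.3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  td <- tidy(fit)
  expect_equal(td$estimate[2], 2.3, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_fit_points, 8L)
  # constant area: undefined slope
  cv2 <- cv; cv2$a_smooth <- rep(0.7e-6, 8)
  expect_config_error(fit_pwv(cv2, fit_range = 1:8))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("segmentation reproduces the area waveform on truth frames", {
  ph <- quiet_phantom(noise_sd = 0)
  phases <- (0:24) / 25
  n <- 256
  mags <- array(0, c(n, n, 25))
  set.seed(33)
  for (f in 1:25)
    mags[, , f] <- Mod(rasterize_state(ph, phases[f], 0)) +
      matrix(rnorm(n * n, 0, 0.05), n, n)
  seed_pt <- round(ph$vessel_center / 24e-3 * n) + n / 2 + 1
  masks <- segment_cine(mags, seed_pt, roi_halfwidth = 14)
  a <- apply(masks, 3, sum) * (24e-3 / n)^2
  tru <- cardiac_waveforms(ph, phases)$a
  expect_gte(cor(a, tru), 0.95)
})

test_that("run summary reports the protocol quantities", {
  # frame rate at the printed mean interval
  expect_equal(round(100 / 0.1072), 933)
  expect_equal(round(100 / 0.100), 1000)
  # temporal blur of 0.75 % of the cycle at RR 107.2 ms
  expect_equal(round(0.0075 * 107.2, 1), 0.8)
})
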