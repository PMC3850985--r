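test_that("cardiac waveforms satisfy the QA construction", {
  ph <- phantom_config()
  w0 <- cardiac_waveforms(ph, 0)
  expect_equal(w0$q, 0)
  expect_equal(w0$a, ph$a_dia)
  p <- seq(0, 0.999, length.out = 2000)
  w <- cardiac_waveforms(ph, p)
  p_up <- ph$upstroke_duration / ph$t_rr_mean
  expect_equal(cardiac_waveforms(ph, p_up)$a, ph$a_peak)
  expect_lte(max(w$a), ph$a_peak)
  # end of upstroke: Q = pwv * (A_peak - A_dia) = 0.276 cm^3/s
  wend <- cardiac_waveforms(ph, p_up * (1 - 1e-9))
  expect_equal(wend$q * 1e6, 0.276, tolerance = 1e-6)
  # least-squares slope through the upstroke equals pwv_true to < 0.1 %
  up <- p < p_up
  slope <- coef(lm(w$q[up] ~ w$a[up]))[2]
  expect_equal(unname(slope), ph$pwv_true, tolerance = 1e-3)
})

test_that("rasterized state encodes velocity in phase", {
  ph <- quiet_phantom(vessel_center = c(0, 0))
  # flow compensation: zero phase everywhere
  i0 <- rasterize_state(ph, 0.05, 0)
  expect_lt(max(abs(Arg(i0[Mod(i0) > 0]))), 1e-12)
  # centre-pixel phase = 2*pi*m1*v_max, v_max = 2*Q/A (parabolic profile)
  w <- cardiac_waveforms(ph, 0.05)
  vmax <- 2 * w$q / w$a
  ip <- rasterize_state(ph, 0.05, 0.3)
  ctr <- ph$grid_hi / 2 + 1
  expect_equal(Arg(ip[ctr, ctr]), 2 * pi * 0.3 * vmax, tolerance = 1e-6)
  # antisymmetry under m1 negation
  im <- rasterize_state(ph, 0.05, -0.3)
  expect_equal(Arg(im[ctr, ctr]), -Arg(ip[ctr, ctr]), tolerance = 1e-12)
  # rasterized lumen area matches the waveform area to < 1 %
  lum <- Mod(ip) > 1.5 * ph$tissue_signal
  cov <- disk_area <- sum(Mod(i0) > 0.5 * (ph$tissue_signal + ph$lumen_signal))
  a_pix <- sum(Mod(i0) >= 0.5 * (ph$tissue_signal + ph$lumen_signal)) *
    (24e-3 / ph$grid_hi)^2
  expect_equal(a_pix, w$a, tolerance = 0.01)
})

test_that("velocity aliasing triggers a warning", {
  ph <- quiet_phantom(pwv_true = 40)     # drives vbar far beyond VENC
  expect_warning(rasterize_state(ph, 0.07, 0.3), "aliasing")
})

test_that("static phantom yields identical projections at equal angles", {
  acq <- small_acq(n_proj = 6, m1_values = c(0, 0.3, -0.3))
  ph <- static_phantom(noise_sd = 0)
  traj <- radial_trajectory(acq, angles = rep(c(40, 130), 3))
  sim <- simulate_acquisition(ph, acq, traj)
  k <- sim$kspace[[1]]
  expect_equal(k[, 3], k[, 1], tolerance = 1e-6)
  expect_equal(k[, 4], k[, 2], tolerance = 1e-6)
})

test_that("heartbeat count over 48 s matches the interval statistics", {
  ph <- phantom_config()
  set.seed(7)
  tg <- radialpwv:::draw_beats(ph, 48)
  n48 <- sum(tg <= 48) - 1            # intervals fully inside 48 s
  expect_equal(n48, 48 / 0.1072, tolerance = 0.02)
})

test_that("simulated noise matches the configured variance", {
  acq <- small_acq(n_proj = 300)
  ph <- quiet_phantom(tissue_signal = 0, lumen_signal = 0, inflow_beta = 0,
                      noise_sd = 2e-3)
  sim <- simulate_acquisition(ph, acq, seed = 3)
  z <- unlist(sim$kspace)
  v <- mean(Mod(z)^2)
  expect_equal(v, (2e-3 * sim$s_ref)^2, tolerance = 0.05)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  acq <- small_acq(n_proj = 120)
  ph <- phantom_config()
  s1 <- simulate_acquisition(ph, acq, seed = 5)
  s2 <- simulate_acquisition(ph, acq, seed = 5)
  expect_identical(s1$kspace, s2$kspace)
  expect_identical(s1$ground_truth$trigger_times, s2$ground_truth$trigger_times)
  s3 <- simulate_acquisition(ph, acq, seed = 6)
  expect_false(identical(s1$kspace, s3$kspace))
})

test_that("forward model is linear in the lumen signal", {
  acq <- small_acq(n_proj = 40)
  mk <- function(ls) {
    sim <- simulate_acquisition(
      static_phantom(noise_sd = 0, lumen_signal = ls, inflow_beta = 0),
      acq, seed = 2)
    sim$kspace[[1]]
  }
  k0 <- mk(0); k1 <- mk(2); k2 <- mk(4)
  expect_equal(k2 - k0, 2 * (k1 - k0), tolerance = 1e-9)
})

test_that("ground truth exposes triggers, respiration and the field map", {
  acq <- small_acq(n_proj = 200)
  sim <- simulate_acquisition(phantom_config(), acq, seed = 1)
  gt <- sim$ground_truth
  expect_true(all(diff(gt$trigger_times) >
                    sim$phantom$t_rr_mean - 5 * sim$phantom$t_rr_sd))
  expect_true(all(diff(gt$trigger_times) <
                    sim$phantom$t_rr_mean + 5 * sim$phantom$t_rr_sd))
  expect_gt(nrow(gt$resp_intervals), 0)
  expect_equal(dim(gt$b0_hz_true), c(256, 256))
  expect_equal(max(gt$b0_hz_true), sim$phantom$b0_peak, tolerance = 0.01)
  expect_equal(nrow(gt$per_projection), 3 * 200)
})
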