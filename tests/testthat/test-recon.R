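test_that("Pipe weights respect coincident-sample symmetry", {
  single <- pipe_dcf(0, 0, matrix = 32)
  pair <- pipe_dcf(c(0, 0), c(0, 0), matrix = 32)
  expect_equal(pair$w, rep(single$w / 2, 2), tolerance = 1e-6)
  expect_config_error(pipe_dcf(numeric(0), numeric(0), 32))
})

test_that("Pipe weights are flat on a uniform Cartesian grid", {
  g <- expand.grid(kx = -8:7, ky = -8:7)
  d <- pipe_dcf(g$kx, g$ky, matrix = 32)
  interior <- abs(g$kx) <= 5 & abs(g$ky) <= 5
  w <- d$w[interior]
  expect_lt((max(w) - min(w)) / mean(w), 0.01)
})

test_that("Pipe weights follow the radial ramp and converge monotonically", {
  u <- uniform_radial(502)
  d <- pipe_dcf(u$kx, u$ky, matrix = 160)
  kk <- sqrt(u$kx^2 + u$ky^2)
  sel <- kk > 10 & kk < 75
  r <- d$w[sel] / kk[sel]
  r <- r / median(r)
  expect_lt(sqrt(mean((r - 1)^2)), 0.10)
  expect_true(all(diff(d$convergence[1:10]) < 0))
})

test_that("gridded adjoint agrees with the direct adjoint DFT", {
  set.seed(11)
  n <- 32
  ang <- golden_angles(110)
  kx <- as.vector(outer(-12:15, cos(ang * pi / 180)))
  ky <- as.vector(outer(-12:15, sin(ang * pi / 180)))
  s <- complex(real = rnorm(length(kx)), imaginary = rnorm(length(kx)))
  w <- rep(1, length(kx))
  a_fast <- gridded_adjoint(s, kx, ky, w, n)
  a_dir <- radialpwv:::nudft_adjoint_direct(s, kx, ky, n)
  expect_lt(max(Mod(a_fast - a_dir)) / max(Mod(a_dir)), 1e-3)
  # linearity
  s2 <- complex(real = rnorm(length(kx)), imaginary = rnorm(length(kx)))
  lhs <- gridded_adjoint(3 * s + s2, kx, ky, w, n)
  rhs <- 3 * a_fast + gridded_adjoint(s2, kx, ky, w, n)
  expect_lt(max(Mod(lhs - rhs)) / max(Mod(lhs)), 1e-9)
})

test_that("forward NUFFT agrees with the direct DFT", {
  set.seed(12)
  n <- 32
  img <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  ang <- golden_angles(90)
  kx <- as.vector(outer(-12:15, cos(ang * pi / 180)))
  ky <- as.vector(outer(-12:15, sin(ang * pi / 180)))
  s_fast <- nufft_forward(img, kx, ky)
  s_dir <- radialpwv:::nudft_forward_direct(img, kx, ky)
  expect_lt(max(Mod(s_fast - s_dir)) / max(Mod(s_dir)), 1e-3)
})

test_that("point-spread function of full sampling is sharply peaked", {
  u <- uniform_radial(502, n_readout = 90)
  d <- pipe_dcf(u$kx, u$ky, 160)
  img <- Mod(gridded_adjoint(rep(1 + 0i, length(u$kx)), u$kx, u$ky, d, 160))
  ctr <- 81
  peak <- img[ctr, ctr]
  img[(ctr - 3):(ctr + 3), (ctr - 3):(ctr + 3)] <- 0
  expect_gte(peak / max(img), 10)
})

test_that("an analytic disk reconstructs against its rasterization", {
  n <- 64
  R <- 0.2                                 # FOV units
  u <- uniform_radial(210, n_readout = 64, idx_echo = 32)
  kk <- sqrt(u$kx^2 + u$ky^2)
  x <- 2 * pi * R * kk
  s <- ifelse(kk < 1e-9, pi * R^2, pi * R^2 * 2 * besselJ(x, 1) / pmax(x, 1e-12))
  d <- pipe_dcf(u$kx, u$ky, n)
  rec <- Mod(gridded_adjoint(s, u$kx, u$ky, d, n))
  tru <- radialpwv:::disk_coverage(0, 0, R, n)
  # the exact (direct-DFT) reconstruction of the same analytic samples is
  # the band-limited reference; the rasterized disk differs from any
  # band-limited image by the Gibbs floor (~6 % at this matrix)
  oracle <- Mod(radialpwv:::nudft_adjoint_direct(s * d$w, u$kx, u$ky, n))
  expect_lt(nrmse(scale_match(rec, oracle), oracle), 0.05)
  e_rec <- nrmse(scale_match(rec, tru), tru)
  e_orc <- nrmse(scale_match(oracle, tru), tru)
  expect_lt(abs(e_rec - e_orc), 0.005)
  expect_lt(e_rec, 0.08)
})

test_that("two-echo field mapping recovers known offsets", {
  n <- 64
  mag <- radialpwv:::ellipse_coverage(0, 0, 0.4, 0.35, n)
  # uniform 600 Hz: phase difference 1.885 rad at dTE = 0.5 ms
  i1 <- mag * exp(0i)
  i2 <- mag * exp(2i * pi * 600 * 0.5e-3)
  om <- b0_map(i1, i2, 0.5e-3)
  expect_equal(median(om$hz[om$mask]), 600, tolerance = 1e-6)
  expect_equal(2 * pi * 600 * 0.5e-3, 1.885, tolerance = 1e-3)
  expect_false(om$unwrapped)
  # identical images: zero map
  expect_equal(max(abs(b0_map(i1, i1, 0.5e-3)$hz)), 0)
  # 1100 Hz blob wraps; spatial unwrapping recovers it
  g <- radialpwv:::grid_coords(n)
  blob <- 1100 * exp(-outer(g, g, function(a, b) a^2 + b^2) / (2 * 0.12^2))
  i2w <- mag * exp(2i * pi * blob * 0.5e-3)
  omw <- b0_map(i1, i2w, 0.5e-3)
  expect_true(omw$unwrapped)
  expect_equal(max(omw$hz), 1100, tolerance = 0.02)
  expect_config_error(b0_map(i1, i2, 0))
})

test_that("conjugate phase reduces to the plain adjoint for a zero map", {
  set.seed(13)
  n <- 32
  ns <- 260
  kx <- runif(ns, -14, 14); ky <- runif(ns, -14, 14)
  s <- complex(real = rnorm(ns), imaginary = rnorm(ns))
  t <- 1.2e-3 + runif(ns, 0, 1.1e-3)
  w <- pipe_dcf(kx, ky, n)
  plain <- gridded_adjoint(s, kx, ky, w, n)
  cp0 <- conjugate_phase_recon(s, kx, ky, t, w, matrix(0, n, n), 8, n)
  expect_identical(cp0, plain)
})

test_that("a spatially uniform offset matches its closed form", {
  set.seed(14)
  n <- 32
  ns <- 260
  kx <- runif(ns, -14, 14); ky <- runif(ns, -14, 14)
  s <- complex(real = rnorm(ns), imaginary = rnorm(ns))
  nr <- 26
  t <- rep(1.2e-3 + (0:(nr - 1)) / 75800, length.out = ns)
  w <- pipe_dcf(kx, ky, n)
  om0 <- 2 * pi * 300
  cp <- conjugate_phase_recon(s, kx, ky, t, w, matrix(om0, n, n), 8, n)
  ref <- gridded_adjoint(s * exp(-1i * om0 * t), kx, ky, w, n)
  expect_lt(max(Mod(cp - ref)) / max(Mod(ref)), 1e-6)
  expect_config_error(conjugate_phase_recon(s, kx, ky, t, w,
                                            matrix(om0, n, n), 0, n))
})

test_that("more time segments approach the exact conjugate-phase evaluation", {
  set.seed(15)
  n <- 32
  ns <- 300
  kx <- runif(ns, -14, 14); ky <- runif(ns, -14, 14)
  s <- complex(real = rnorm(ns), imaginary = rnorm(ns))
  nr <- 30
  t <- rep(1.2e-3 + (0:(nr - 1)) / 25000, length.out = ns)  # long readout
  w <- pipe_dcf(kx, ky, n)
  g <- radialpwv:::grid_coords(n)
  om <- 2 * pi * 600 * exp(-outer(g, g, function(a, b) a^2 + b^2) / (2 * 0.1^2))
  exact <- radialpwv:::conjugate_phase_exact(s, kx, ky, t, w, om)
  errs <- sapply(c(4, 8, 16), function(L)
    nrmse(conjugate_phase_recon(s, kx, ky, t, w, om, L, n), exact))
  expect_true(all(diff(errs) < 0))
  # the gridded path itself is accurate at this size
  expect_lt(errs[3], 5e-3)
})

test_that("reconstruction energy scales linearly with noise variance", {
  set.seed(16)
  u <- uniform_radial(160, n_readout = 64, idx_echo = 32)
  d <- pipe_dcf(u$kx, u$ky, 64)
  vars <- c(1, 2, 4, 8)
  energy <- sapply(vars, function(v) {
    s <- complex(real = rnorm(length(u$kx), 0, sqrt(v / 2)),
                 imaginary = rnorm(length(u$kx), 0, sqrt(v / 2)))
    sum(Mod(gridded_adjoint(s, u$kx, u$ky, d, 64))^2)
  })
  expect_gt(summary(lm(energy ~ vars))$r.squared, 0.99)
})

test_that("off-resonance correction deblurs the severe 600 Hz regime", {
  ph <- quiet_phantom(b0_peak = 600, noise_sd = 1e-4)
  acq <- small_acq(n_proj = 502)
  pr <- simulate_b0_probe(ph, acq, n_spokes = 502, seed = 21)
  kx <- as.vector(pr$traj$kx); ky <- as.vector(pr$traj$ky)
  t <- rep(pr$traj$t_read, times = 502)
  d <- pipe_dcf(kx, ky, 160)
  om_true <- 2 * pi * b0_field_true(ph, 160, acq$fov)
  un <- Mod(gridded_adjoint(as.vector(pr$s1), kx, ky, d, 160))
  co <- Mod(conjugate_phase_recon(as.vector(pr$s1), kx, ky, t, d, om_true,
                                  8, 160))
  tru <- Mod(rasterize_state(ph, 0.5, 0, n = 160))
  # evaluate where the off-resonance acts: the vessel neighbourhood
  roi_i <- 94 + (-16:16); roi_j <- 88 + (-16:16)
  sub <- function(x) x[roi_i, roi_j]
  e_un <- nrmse(sub(scale_match(un, tru)), sub(tru))
  e_co <- nrmse(sub(scale_match(co, tru)), sub(tru))
  expect_lt(e_co, e_un)
  expect_lt(e_co, 0.7 * e_un)    # >= 30 % NRMSE drop
})

test_that("cine reconstruction fills and flags empty frames", {
  acq <- small_acq(n_proj = 60)
  ph <- static_phantom(noise_sd = 1e-5)
  sim <- simulate_acquisition(ph, acq, seed = 22)
  base <- tibble::tibble(frame = rep(c(1L, 2L, 4L), each = 20),
                         projection = rep(1:60 * 0 + seq_len(60)))
  base$projection <- c(1:20, 21:40, 41:60)
  fs <- structure(base, class = c("frame_selection", class(base)),
                  n_frames = 4, window_halfwidth = 5e-4, empty_frames = 3L,
                  triggers = c(0, 1))
  cine <- reconstruct_cine(sim, fs, zero_fill_matrix = 192)
  expect_equal(cine$flagged_frames, 3L)
  expect_equal(dim(cine$frames[[1]]), c(192, 192, 4))
  # the empty frame was filled from a populated neighbour (frame 2 or 4)
  filled <- cine$frames[[1]][, , 3]
  expect_true(identical(filled, cine$frames[[1]][, , 2]) ||
                identical(filled, cine$frames[[1]][, , 4]))
  # static phantom: all populated frames agree to reconstruction accuracy
  m1 <- Mod(cine$frames[[1]][, , 1]); m2 <- Mod(cine$frames[[1]][, , 2])
  expect_lt(nrmse(m1, m2), 0.2)      # different angle subsets, same object
})

test_that("zero-filling interpolates without changing pixel values", {
  set.seed(23)
  img <- matrix(complex(real = rnorm(64 * 64), imaginary = rnorm(64 * 64)),
                64, 64)
  z <- zero_fill(img, 128)
  expect_equal(dim(z), c(128, 128))
  # original samples sit on every other output pixel
  expect_equal(z[seq(1, 127, by = 2), seq(1, 127, by = 2)], img,
               tolerance = 1e-9)
  expect_config_error(zero_fill(img, 32))
})
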