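test_that("moving-average correction removes static structure, preserves the mean", {
  set.seed(1)
  static <- matrix(runif(64, 10, 20), 8, 8)
  stack <- replicate(12, static, simplify = FALSE)
  out <- moving_average_correction(stack, window_frames = 12)
  for (fr in out) expect_equal(fr, matrix(mean(static), 8, 8), tolerance = 1e-12)

  expect_warning(deg <- moving_average_correction(stack, 1), "degenerate")
  expect_equal(deg[[3]], matrix(mean(static), 8, 8), tolerance = 1e-12)

  rand <- replicate(20, matrix(rnorm(64, 50, 5), 8, 8), simplify = FALSE)
  corr <- moving_average_correction(rand, 5)
  expect_equal(mean(simplify2array(corr)), mean(simplify2array(rand)),
               tolerance = 1e-10)
  expect_error(moving_average_correction(rand, 21), "between")
})

test_that("FFT autocorrelation equals the brute-force double loop", {
  set.seed(2)
  frames <- replicate(3, matrix(rpois(64, 30), 8, 8), simplify = FALSE)
  acf <- compute_acf(frames, max_xi = 5, max_psi = 5)
  oracle <- brute_force_acf(frames, 5, 5)
  expect_equal(unname(acf$values), oracle, tolerance = 1e-10)

  # a larger single frame too
  f16 <- list(matrix(rnorm(256, 100, 10), 16, 16))
  acf16 <- compute_acf(f16, max_xi = 7, max_psi = 4)
  expect_equal(unname(acf16$values), brute_force_acf(f16, 7, 4),
               tolerance = 1e-10)

  # exact point symmetry
  v <- acf$values
  expect_equal(v, v[rev(seq_len(nrow(v))), rev(seq_len(ncol(v)))],
               tolerance = 1e-12, ignore_attr = TRUE)

  # constant image: zero ACF, flagged
  const <- compute_acf(list(matrix(5, 8, 8)), max_xi = 3, max_psi = 3)
  expect_true(const$flag_zero_variance)
  expect_true(all(const$values == 0))
})

test_that("immobile and empty scenes behave as closed forms predict", {
  sc <- rics_scan_config(frame_size = 32)
  # no particles: mean equals the background offset
  empty <- simulate_rics_image_series(sc, 0, 0, n_frames = 4, seed = 3,
                                      offset = 2)
  m <- mean(simplify2array(empty$frames))
  expect_equal(m, 2, tolerance = 4 * sqrt(2 / (4 * 32^2)))

  # zero diffusion: noiseless frames are identical
  frozen <- simulate_rics_image_series(sc, 40, 0, n_frames = 3, seed = 4,
                                       noiseless = TRUE, offset = 0)
  expect_equal(frozen$frames[[1]], frozen$frames[[2]], tolerance = 1e-12)
  expect_equal(frozen$frames[[2]], frozen$frames[[3]], tolerance = 1e-12)

  # one immobile particle centered on a pixel: its pixel reads `brightness`
  box_xy <- max(sc$image_width_um, 4 * sc$w0_um)
  x0 <- (box_xy - sc$image_width_um) / 2
  px <- sc$pixel_size_nm / 1000
  ix <- 16 # 0-based pixel index
  ctr <- c(x0 + (ix + 0.5) * px, x0 + (ix + 0.5) * px, 4 * sc$wz_um / 2)
  one <- simulate_rics_image_series(sc, 1, 0, brightness = 7, n_frames = 2,
                                    positions = matrix(ctr, 1), offset = 0,
                                    noiseless = TRUE)
  expect_equal(one$frames[[1]][ix + 1, ix + 1], 7, tolerance = 1e-9)
  # and its time average under shot noise converges to brightness
  many <- simulate_rics_image_series(sc, 1, 0, brightness = 7, n_frames = 60,
                                     positions = matrix(ctr, 1), offset = 0,
                                     seed = 5)
  peak <- mean(vapply(many$frames, function(f) f[ix + 1, ix + 1], numeric(1)))
  expect_lt(abs(peak - 7), 3 * sqrt(7 / 60))

  expect_error(simulate_rics_image_series(sc, 1, 0, box_z_um = 0.5), "waists")
})

test_that("the immobile limit recovers G0 = gamma / N on uncorrected stacks", {
  sc <- rics_scan_config(frame_size = 128)
  np <- particles_for_focal_n(20, sc)
  # independent immobile particle fields; the per-frame ACF average pools
  # their speckle ensembles
  frames <- unlist(lapply(1:10, function(s) {
    simulate_rics_image_series(sc, np, 0, n_frames = 1, seed = s,
                               noiseless = TRUE, offset = 0)$frames
  }), recursive = FALSE)
  fit <- fit_diffusion_model(compute_acf(frames, max_xi = 33, max_psi = 9),
                             sc)
  expect_lt(fit$D_um2_s, 0.1) # immobile
  expect_equal(fit$G0 * 20, sc$gamma, tolerance = 0.1)
})

test_that("fitted amplitude is inverse in N and D matches a fine-step oracle", {
  sc <- rics_scan_config(frame_size = 64)
  fit_one <- function(N, seed, substeps = 1) {
    ser <- simulate_rics_image_series(sc, particles_for_focal_n(N, sc), 1,
                                      n_frames = 25, seed = seed,
                                      substeps_per_line = substeps)
    fit_diffusion_model(compute_acf(ser, max_xi = 33, max_psi = 9), sc)
  }
  seeds <- 1:6
  g_small <- vapply(seeds, function(s) fit_one(10, s)$G0, numeric(1))
  g_big <- vapply(seeds, function(s) fit_one(20, s + 100)$G0, numeric(1))
  expect_equal(median(g_small) / median(g_big), 2, tolerance = 0.1)

  # update cadence: one step per line vs 10x finer substeps agree on D
  d_coarse <- vapply(seeds, function(s) fit_one(15, s)$D_um2_s, numeric(1))
  d_fine <- vapply(seeds, function(s) fit_one(15, s, substeps = 10)$D_um2_s,
                   numeric(1))
  expect_equal(median(d_coarse), median(d_fine), tolerance = 0.25)
})

test_that("particle numbers convert to concentrations dimensionally", {
  sc <- rics_scan_config()
  n_a <- 6.02214076e23
  v_l <- focal_volume(sc) * 1e-15
  expect_equal(particles_to_concentration(v_l * n_a * 1e-9, sc), 1,
               tolerance = 1e-12)
  # doubling w0 with wz = 3 w0 scales V_eff by 8, concentration by 1/8
  sc2 <- rics_scan_config(w0_um = 0.5)
  expect_equal(particles_to_concentration(5, sc2),
               particles_to_concentration(5, sc) / 8, tolerance = 1e-12)
  set.seed(6)
  for (n in runif(5, 1, 100)) {
    expect_equal(particles_to_concentration(n, sc), n / (v_l * n_a) * 1e9)
  }
  expect_error(particles_to_concentration(0, sc), "positive")
  # monotone in N, decreasing in focal volume
  expect_true(particles_to_concentration(10, sc) >
                particles_to_concentration(5, sc))
  expect_true(particles_to_concentration(10, sc2) <
                particles_to_concentration(10, sc))
})
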