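test_that("background subtraction clips at zero and matches the elementwise oracle", {
  refs <- test_refs()
  s <- simulate_well_spectrum(c(1e-6, 0, 0), 2e4, refs, seed = 1)
  expect_equal(subtract_background(s, s)$counts, rep(0, 176))

  zero <- emission_spectrum("blank", rep(0, 176))
  expect_equal(subtract_background(s, zero)$counts, s$counts)

  b <- simulate_well_spectrum(c(0, 0, 0), 2e4, refs, seed = 2)
  got <- subtract_background(s, b)
  oracle <- numeric(176)
  for (i in 1:176) oracle[i] <- max(s$counts[i] - b$counts[i], 0)
  expect_equal(got$counts, oracle)
  expect_equal(attr(got, "n_clipped"), sum(s$counts - b$counts < 0))

  short <- s
  short$wavelengths <- short$wavelengths + 2
  expect_error(subtract_background(s, short), "grid")
})

test_that("smoothing is exact on polynomials and identity at window 1", {
  wl <- wavelength_grid()
  poly <- emission_spectrum("p", 5 + 0.01 * (wl - 450) + 1e-4 * (wl - 450)^2)
  expect_equal(smooth_spectrum(poly, window = 11, polyorder = 3)$counts,
               poly$counts, tolerance = 1e-8)
  expect_equal(smooth_spectrum(poly, window = 1, polyorder = 0)$counts,
               poly$counts)
  expect_error(smooth_spectrum(poly, window = 4), "odd")
  expect_error(smooth_spectrum(poly, window = 3, polyorder = 5), "polyorder")
  expect_error(smooth_spectrum(poly, window = 177), "grid")
})

test_that("smoothing reduces noise variance around a Gaussian peak", {
  wl <- wavelength_grid()
  truth <- 500 * exp(-(wl - 572)^2 / (2 * 15^2))
  set.seed(4)
  worse <- 0
  for (i in 1:100) {
    noisy <- emission_spectrum("n", rpois(176, truth))
    sm <- smooth_spectrum(noisy, window = 9, polyorder = 3)
    if (mean((sm$counts - truth)^2) >= mean((noisy$counts - truth)^2)) {
      worse <- worse + 1
    }
  }
  expect_equal(worse, 0)
})

test_that("unmixing recovers interior solutions to the linear-solve oracle", {
  refs <- test_refs()
  a <- refs$components

  # single component, noiseless
  y <- emission_spectrum("g", 2 * a[, "green"])
  u <- unmix_spectrum(y, refs)
  expect_equal(unname(u$coefficients), c(0, 2, 0, 0), tolerance = 1e-10)
  expect_lt(u$residual_norm, 1e-10)

  # full interior mixture vs unconstrained normal-equations oracle
  cvec <- c(0.5, 1.0, 0.25, 0.75)
  y2 <- emission_spectrum("mix", as.numeric(a %*% cvec))
  u2 <- unmix_spectrum(y2, refs)
  oracle <- as.numeric(solve(crossprod(a), crossprod(a, y2$counts)))
  expect_equal(unname(u2$coefficients), oracle, tolerance = 1e-8)
  expect_equal(unname(u2$coefficients), cvec, tolerance = 1e-8)

  # nonnegativity binds on an impossible (negative) spectrum
  neg <- y$counts - 2 * a[, "green"] * 2 # = -2 x green
  neg_s <- emission_spectrum("neg", pmax(-(2 * a[, "green"]), 0) + 0)
  u3 <- unmix_spectrum(emission_spectrum("z", rep(0, 176)), refs)
  expect_true(all(u3$coefficients >= 0))
  # ols mode agrees with nnls on interior problems
  u4 <- unmix_spectrum(y2, refs, method = "ols")
  expect_equal(u4$coefficients, u2$coefficients, tolerance = 1e-8)
})

test_that("unmixing is scale-equivariant and conserves counts", {
  refs <- test_refs()
  a <- refs$components
  cvec <- c(0.8, 2, 1, 0.5)
  base <- as.numeric(a %*% cvec)
  u1 <- unmix_spectrum(emission_spectrum("w", base), refs)
  u5 <- unmix_spectrum(emission_spectrum("w", 5 * base), refs)
  expect_equal(5 * u1$coefficients, u5$coefficients, tolerance = 1e-8)

  # conservation: component counts plus residual account for the total
  set.seed(8)
  noisy <- emission_spectrum("w", rpois(176, 100 * base))
  u <- unmix_spectrum(noisy, refs)
  recon <- as.numeric(a %*% u$coefficients)
  expect_equal(sum(u$coefficients) + sum(noisy$counts - recon),
               sum(noisy$counts), tolerance = 1e-8)
})

test_that("ill-conditioned designs are refused with the colliding pair named", {
  close_pair <- list(qd_color("a", 560, 30), qd_color("b", 560.0005, 30))
  refs <- make_reference_spectra(close_pair)
  y <- emission_spectrum("w", refs$components[, "a"])
  expect_error(unmix_spectrum(y, refs, max_condition = 1e4), "a.*b|collide")
})

test_that("calibration fits match the closed-form least-squares oracle", {
  conc <- c(13.1, 9.83, 7.37, 5.53, 4.15, 3.11, 2.33)
  exact <- fit_calibration(conc, 5 * conc)
  expect_equal(exact$slope, 5, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1)

  set.seed(12)
  counts <- 3e5 * conc + 100 + rnorm(7, 0, 50)
  fit <- fit_calibration(conc, counts)
  # closed-form simple-regression oracle
  slope_o <- sum((conc - mean(conc)) * (counts - mean(counts))) /
    sum((conc - mean(conc))^2)
  int_o <- mean(counts) - slope_o * mean(conc)
  expect_equal(fit$slope, slope_o, tolerance = 1e-10)
  expect_equal(fit$intercept, int_o, tolerance = 1e-10)

  two <- fit_calibration(c(1, 3), c(10, 20))
  expect_equal(two$slope, 5)
  expect_equal(two$intercept, 5)
  expect_error(fit_calibration(c(2, 2), c(1, 2)), "identical")
  expect_warning(fit_calibration(c(1, 2, 3), c(9, 5, 1)), "slope")
})

test_that("counts round-trip through the calibration to nmol per mg", {
  refs <- test_refs()
  curves <- test_calibrations(refs)
  # a result sitting exactly at a calibration point returns that concentration
  cu <- curves$green
  target_conc <- 5.53
  counts_at <- cu$slope * target_conc + cu$intercept
  res <- structure(list(well_id = "w",
                        coefficients = c(autofluorescence = 0,
                                         green = counts_at, yellow = 0, red = 0),
                        per_color_counts = c(green = counts_at, yellow = 0,
                                             red = 0),
                        autofluorescence_counts = 0, residual_norm = 0,
                        method = "nnls"), class = "qd_unmix")
  out <- counts_to_nmol_per_mg(res, curves)
  expect_equal(out$nmol_per_mg[out$color == "green"], target_conc * 150,
               tolerance = 1e-10)

  zero <- structure(list(well_id = "w",
                         coefficients = c(autofluorescence = 0, green = 0,
                                          yellow = 0, red = 0),
                         per_color_counts = c(green = 0, yellow = 0, red = 0),
                         autofluorescence_counts = 0, residual_norm = 0,
                         method = "nnls"), class = "qd_unmix")
  zc <- lapply(curves, function(cu) { cu$intercept <- 0; cu })
  expect_equal(counts_to_nmol_per_mg(zero, zc)$nmol_per_mg, rep(0, 3))
  expect_error(counts_to_nmol_per_mg(res, curves["green"]), "missing")
})

test_that("known amounts are recovered within Poisson error", {
  refs <- test_refs()
  # exact calibration so the ensemble bias isolates the unmixing chain
  curves <- lapply(default_qd_colors(), function(cc) {
    calibrate_plate(simulate_calibration_plate(cc, refs = refs,
                                               noiseless = TRUE), refs)
  })
  truth_nmol <- 0.2
  set.seed(21)
  est <- replicate(100, {
    s <- simulate_well_spectrum(c(truth_nmol, 0, 0), 5e4, refs)
    u <- unmix_spectrum(s, refs)
    counts_to_nmol_per_mg(u, curves, tissue_mass_mg = 1,
                          floor_negative = FALSE)$nmol_per_mg[1]
  })
  # Poisson SE of the integrated green counts, in nmol
  se <- sqrt(truth_nmol * refs$brightness[["green"]]) / refs$brightness[["green"]]
  expect_lt(abs(mean(est) - truth_nmol), 3 * se)
})

test_that("replicate wells average with SEM and guard against mixing samples", {
  tab <- data.frame(well_id = paste0("w", 1:5), color = "green",
                    nmol_per_mg = c(1, 2, 3, 4, 5))
  avg <- average_replicate_wells(tab, "s1")
  expect_equal(avg$nmol_per_mg, 3)
  expect_equal(avg$sem, sd(1:5) / sqrt(5))
  expect_equal(avg$n_wells, 5)

  same <- tab
  same$nmol_per_mg <- 2
  expect_equal(average_replicate_wells(same, "s1")$sem, 0)

  one <- average_replicate_wells(tab[1, ], "s1")
  expect_true(one$flag_single_well)
  expect_true(is.na(one$sem))

  mixed <- cbind(tab, sample_id = c("a", "a", "b", "b", "b"))
  expect_error(average_replicate_wells(mixed), "different samples")
})

test_that("detection limit is 3 sigma of the blanks, monotone in blank noise", {
  # noiseless blanks: zero variance -> limit 0 with warning
  flat <- data.frame(color = "green", nmol_per_mg = rep(0, 25))
  expect_warning(dl0 <- detection_limit(flat), "zero variance")
  expect_equal(dl0$limit_fmol_per_mg, 0)

  # definitional: blanks whose sd equals the signal at X fmol/mg -> limit 3X
  x_fmol <- 0.4
  set.seed(31)
  blanks <- data.frame(color = "green",
                       nmol_per_mg = rnorm(400, 0, x_fmol * 1e-6))
  dl <- detection_limit(blanks)
  expect_equal(dl$limit_fmol_per_mg, 3 * x_fmol, tolerance = 0.25)

  # monotone nondecreasing in blank sd over a noise grid
  set.seed(32)
  base <- rnorm(200)
  limits <- vapply(c(0.1, 0.3, 1, 3, 10) * 1e-6, function(s) {
    detection_limit(data.frame(color = "g", nmol_per_mg = base * s))$limit_fmol_per_mg
  }, numeric(1))
  expect_true(all(diff(limits) > 0))
  expect_error(detection_limit(data.frame(color = "g", nmol_per_mg = 1:5)),
               "at least 20")
})

test_that("the full chain is the identity on noiseless wells", {
  refs <- test_refs()
  # exact calibration from noiseless plates
  curves <- lapply(default_qd_colors(), function(cc) {
    calibrate_plate(simulate_calibration_plate(cc, refs = refs,
                                               noiseless = TRUE), refs)
  })
  amounts <- c(green = 0.02, yellow = 0.005, red = 0.013) # nmol in well
  s <- simulate_well_spectrum(amounts, 0, refs, noiseless = TRUE)
  out <- quantify_wells(list(s), refs, curves, smooth_stage = "none")
  # with 1 mg of tissue in the well, nmol per mg equals nmol in the well
  got <- out$nmol_per_mg[match(names(amounts), out$color)]
  expect_equal(unname(got), unname(amounts), tolerance = 1e-6)
})
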