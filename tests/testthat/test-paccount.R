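test_that("stoichiometric conversion is linear and order preserving", {
  expect_equal(qd_to_p(1), 708)
  expect_equal(qd_to_p(0), 0)
  expect_equal(qd_to_p(0.5), 354)
  x <- sort(runif(20))
  expect_equal(qd_to_p(x), 708 * x)
  expect_true(all(diff(qd_to_p(x)) >= 0))
  expect_error(qd_to_p(-1), "nonnegative")
})

test_that("percent P from QD-apatite follows the 708 ratio", {
  # QD-derived P equal to total P -> 100 %
  expect_equal(as.numeric(percent_p_from_qd(1, 708)), 100)
  # consistency with qd_to_p as the sole P source
  q <- 0.37
  expect_equal(as.numeric(percent_p_from_qd(q, qd_to_p(q))), 100)
  # inputs constructed to give the cross-treatment average of 5.6 %
  q <- 1e-3
  total <- 708 * q / 0.056
  expect_equal(as.numeric(percent_p_from_qd(q, total)), 5.6, tolerance = 1e-12)
  # random inputs against the hand formula
  set.seed(2)
  qs <- runif(50, 0, 1e-2)
  ps <- runif(50, 10, 100)
  expect_equal(as.numeric(percent_p_from_qd(qs, ps)), 100 * 708 * qs / ps)
  expect_error(percent_p_from_qd(1, 0), "positive")
  expect_warning(pp <- percent_p_from_qd(1, 10), "exceeds")
  expect_true(attr(pp, "flag_over_100"))
})

test_that("allocation ratios pair young over established within plates", {
  tab <- data.frame(
    plate_id = rep(c("p1", "p2"), each = 2),
    treatment = "control",
    compartment = rep(c("young", "established"), 2),
    color = "green", injection_age_days = 21L,
    nmol_qd_per_mg = c(2, 4, 3, 3)
  )
  r <- allocation_ratio(tab)
  expect_equal(r$ratio[r$plate_id == "p1"], 0.5)
  expect_equal(r$ratio[r$plate_id == "p2"], 1)

  # scale invariance to per-plate multipliers (extraction efficiency)
  tab2 <- tab
  tab2$nmol_qd_per_mg <- tab$nmol_qd_per_mg * rep(c(7, 0.3), each = 2)
  expect_equal(allocation_ratio(tab2)$ratio, r$ratio)

  # unpaired and zero-denominator plates are excluded and counted
  tab3 <- rbind(tab, data.frame(plate_id = "p3", treatment = "control",
                                compartment = "young", color = "green",
                                injection_age_days = 21L, nmol_qd_per_mg = 1))
  tab3$nmol_qd_per_mg[tab3$plate_id == "p2" &
                        tab3$compartment == "established"] <- 0
  r3 <- allocation_ratio(tab3)
  expect_equal(nrow(r3), 1)
  expect_equal(attr(r3, "n_excluded_unpaired"), 1L)
  expect_equal(attr(r3, "n_excluded_zero_denominator"), 1L)
})

test_that("retention ratios divide hyphal by root concentration", {
  expect_equal(retention_ratio(2, 2)$ratio, 1)
  expect_equal(retention_ratio(0, 5)$ratio, 0)
  set.seed(3)
  h <- runif(30)
  r <- runif(30, 0.1, 2)
  expect_equal(retention_ratio(h, r)$ratio, h / r)
  out <- retention_ratio(c(1, 1), c(0, 2))
  expect_true(out$flag_zero_root[1])
  expect_true(is.na(out$ratio[1]))
})

test_that("absorbance and Cq conversions invert their standard curves", {
  expect_equal(absorbance_to_p(0.05, slope = 0.1, intercept = 0.05)$p_conc, 0)
  expect_equal(absorbance_to_p(0.1 * 7 + 0.02, 0.1, 0.02)$p_conc, 7)
  set.seed(4)
  a <- runif(20)
  expect_equal(absorbance_to_p(a, 0.2, 0.01)$p_conc,
               pmax((a - 0.01) / 0.2, 0))
  expect_error(absorbance_to_p(1, slope = 0), "positive")

  # qPCR: observed internal standard equal to expected -> correction 1
  slope <- -0.3 # log10 copies per cycle
  inter <- 10
  is_cq <- 12
  is_copies <- 10^(slope * is_cq + inter)
  r <- cq_to_copies_per_mg(20, 2, slope, inter,
                           cq_internal_standard = is_cq,
                           expected_is_copies = is_copies)
  expect_equal(r$efficiency_correction, 1)
  expect_equal(r$copies_per_mg, 10^(slope * 20 + inter) / 2)

  # Cq at a calibration anchor returns the anchor copy number
  anchor_cq <- 15
  anchor_copies <- 10^(slope * anchor_cq + inter)
  r2 <- cq_to_copies_per_mg(anchor_cq, 1, slope, inter,
                            cq_internal_standard = is_cq,
                            expected_is_copies = is_copies)
  expect_equal(r2$copies_per_mg, anchor_copies)

  expect_warning(r3 <- cq_to_copies_per_mg(20, 2, slope, inter), "internal")
  expect_true(r3$flag_no_internal_standard)
  expect_equal(r3$efficiency_correction, 1)
})

test_that("fungal abundance transform is a log of mass times copy density", {
  # 1 g of root at 1e6 copies/g -> 6.0 (mass given in mg, copies per mg)
  expect_equal(fungal_abundance_transform(1000, 1000)$log_abundance, 6)
  # scaling mass by 10 adds exactly 1
  base <- fungal_abundance_transform(200, 5e4)$log_abundance
  expect_equal(fungal_abundance_transform(2000, 5e4)$log_abundance, base + 1)
  set.seed(5)
  m <- runif(20, 1, 1000)
  cp <- runif(20, 10, 1e6)
  expect_equal(fungal_abundance_transform(m, cp)$log_abundance,
               log10((m / 1000) * (cp * 1000)))
  out <- fungal_abundance_transform(100, 0)
  expect_true(out$flag_below_detection)
  expect_true(is.na(out$log_abundance))
})

test_that("noise-free synthetic data reproduce every derived quantity", {
  ex <- simulate_experiment(allocation_model(noise_cv = 0, seed = 11))
  tab <- ex$table
  truth <- ex$ground_truth
  # retention ratios equal their planted values
  rr <- retention_ratio(tab$hyphal_conc_per_biovolume,
                        tab$root_conc_per_biovolume)
  expect_equal(rr$ratio, truth$true_retention_ratio, tolerance = 1e-12)
  # percent P recomputed from the table matches the formula everywhere
  pct <- as.numeric(percent_p_from_qd(tab$nmol_qd_per_mg,
                                      tab$total_p_nmol_per_mg))
  expect_equal(pct, 100 * 708 * tab$nmol_qd_per_mg / tab$total_p_nmol_per_mg)
})
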