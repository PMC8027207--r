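# Shared fixtures and independent oracles, built in code at test time.

# Reference set and per-color calibrations used across unmixing tests.
test_refs <- function() make_reference_spectra(default_qd_colors())

test_calibrations <- function(refs = test_refs(), seed = 42) {
  set.seed(seed)
  out <- lapply(default_qd_colors(), function(cc) {
    calibrate_plate(simulate_calibration_plate(cc, refs = refs), refs)
  })
  out
}

# Brute-force spatial ACF oracle: direct double loop over all non-wrapping
# pixel pairs, per frame, same normalization as compute_acf (per-frame mean
# subtraction and denominator), averaged over frames. Deliberately naive.
brute_force_acf <- function(frames, max_xi, max_psi) {
  ny <- nrow(frames[[1]])
  nx <- ncol(frames[[1]])
  xis <- -max_xi:max_xi
  psis <- -max_psi:max_psi
  acc <- matrix(0, length(psis), length(xis))
  nf <- 0
  for (fr in frames) {
    mu <- mean(fr)
    if (var(as.numeric(fr)) == 0) next
    nf <- nf + 1
    d <- fr - mu
    for (pi_ in seq_along(psis)) {
      for (xi_ in seq_along(xis)) {
        psi <- psis[pi_]
        xi <- xis[xi_]
        s <- 0
        n <- 0
        for (y in 1:ny) {
          for (x in 1:nx) {
            y2 <- y + psi
            x2 <- x + xi
            if (y2 >= 1 && y2 <= ny && x2 >= 1 && x2 <= nx) {
              s <- s + d[y, x] * d[y2, x2]
              n <- n + 1
            }
          }
        }
        acc[pi_, xi_] <- acc[pi_, xi_] + s / n / mu^2
      }
    }
  }
  acc / nf
}

# Closed-form pooled two-sample Student's t, written out by hand.
hand_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tval, p = 2 * pt(-abs(tval), df = na + nb - 2))
}

# Simulate an ensemble of blank samples (autofluorescence only, five
# replicate wells each) and return their signed calibrated estimates.
simulate_blank_estimates <- function(refs, curves, n_samples = 24,
                                     wells_per_sample = 5, af_amount = 5e4) {
  do.call(rbind, lapply(seq_len(n_samples), function(i) {
    wells <- lapply(seq_len(wells_per_sample), function(j) {
      simulate_well_spectrum(c(0, 0, 0), af_amount, refs,
                             well_id = sprintf("blank%02d_%d", i, j))
    })
    quantify_wells(wells, refs, curves, sample_id = sprintf("blank%02d", i),
                   smooth_stage = "none", floor_negative = FALSE)
  }))
}
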