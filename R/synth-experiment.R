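#' Phenomenological allocation model for the two-host experiment
#'
#' Parameters of the synthetic plate-level experiment: a shared fungal
#' network connects an established root (direct access to the injected
#' QD-apatite) and a young root (access only via the network), under a
#' control or a phosphorus-limited (low-P) treatment. Three QD colors map to
#' injection ages 21 (green), 14 (yellow) and 7 (red) days before harvest.
#' The model is phenomenological: it prescribes expected per-mg QD amounts
#' and their young/established and hyphae/root ratios, not uptake kinetics.
#'
#' @param baseline_transfer_young expected young/established amount ratio in
#'   all cells except the treatment-by-time cell; default 0.85 (young roots
#'   carry ~15 percent less tracer than established roots).
#' @param treatment_time_effect additive increase of the young/established
#'   ratio applied only to the (low-P, 7-day red injection) cell; default
#'   0.5. This is the interaction that emerges at the third injection.
#' @param hyphal_retention_control expected hyphae/root per-biovolume
#'   concentration ratio everywhere except the late low-P young cell;
#'   default 0.9 (slightly below one: near-equal amounts per biovolume).
#' @param hyphal_retention_lowP_young_late expected retention ratio in the
#'   (low-P, young, 7-day) cell; default 0.45 (more transfer, less storage).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   plate-to-plate noise on amounts and concentrations; default 0.3.
#' @param n_plates_per_treatment plates per treatment arm; default 24.
#' @param established_mean_nmol_per_mg expected per-color QD-apatite in the
#'   established root, nmol per mg root; default 1.7e-3.
#' @param total_p_mean_nmol_per_mg expected total P per mg root (all
#'   sources, including the growth substrate); default 65.
#' @param seed integer seed recorded in the model and used by
#'   [simulate_experiment()].
#' @return Object of class `allocation_model` (a validated list).
#' @export
allocation_model <- function(baseline_transfer_young = 0.85,
                             treatment_time_effect = 0.5,
                             hyphal_retention_control = 0.9,
                             hyphal_retention_lowP_young_late = 0.45,
                             noise_cv = 0.3,
                             n_plates_per_treatment = 24,
                             established_mean_nmol_per_mg = 1.7e-3,
                             total_p_mean_nmol_per_mg = 65,
                             seed = 1L) {
  frac <- c(baseline_transfer_young, hyphal_retention_control,
            hyphal_retention_lowP_young_late)
  if (any(frac <= 0 | frac >= 1)) {
    stop("ratio parameters must lie in (0, 1)")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_plates_per_treatment < 2) stop("need at least 2 plates per treatment")
  structure(
    list(baseline_transfer_young = baseline_transfer_young,
         treatment_time_effect = treatment_time_effect,
         hyphal_retention_control = hyphal_retention_control,
         hyphal_retention_lowP_young_late = hyphal_retention_lowP_young_late,
         noise_cv = noise_cv,
         n_plates_per_treatment = as.integer(n_plates_per_treatment),
         established_mean_nmol_per_mg = established_mean_nmol_per_mg,
         total_p_mean_nmol_per_mg = total_p_mean_nmol_per_mg,
         seed = as.integer(seed)),
    class = "allocation_model"
  )
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a plate-level two-host allocation experiment
#'
#' Generates the long-format experiment table the ratio statistics consume:
#' one record per plate x compartment x color, with per-mg QD amounts,
#' total P, tissue masses, and per-biovolume hyphal/root QD concentrations.
#' Expected values follow the [allocation_model()]; realized values are the
#' expectation times mean-one lognormal noise. The treatment-by-time
#' interaction (more tracer to the P-limited young root) is applied only at
#' the third (7-day, red) injection.
#'
#' @param model an [allocation_model()].
#' @return Object of class `qd_experiment`: list with `table` (data.frame),
#'   `ground_truth` (data.frame of expected values and true ratios keyed by
#'   plate_id/compartment/color), and `model`.
#' @export
#' @examples
#' ex <- simulate_experiment(allocation_model(noise_cv = 0, seed = 7))
#' head(ex$table)
simulate_experiment <- function(model = allocation_model()) {
  stopifnot(inherits(model, "allocation_model"))
  set.seed(model$seed)
  treatments <- c("control", "low-P")
  compartments <- c("established", "young")
  colors <- c(green = 21L, yellow = 14L, red = 7L)
  n <- model$n_plates_per_treatment

  grid <- expand.grid(
    color = names(colors),
    compartment = compartments,
    plate = seq_len(n),
    treatment = treatments,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$plate_id <- sprintf("%s_%02d", ifelse(grid$treatment == "control", "C", "L"),
                           grid$plate)
  grid$injection_age_days <- colors[grid$color]

  # expected young/established ratio per cell
  true_ratio <- rep(model$baseline_transfer_young, nrow(grid))
  late_lowp <- grid$treatment == "low-P" & grid$color == "red"
  true_ratio[late_lowp] <- true_ratio[late_lowp] + model$treatment_time_effect

  expected_amount <- ifelse(
    grid$compartment == "established",
    model$established_mean_nmol_per_mg,
    model$established_mean_nmol_per_mg * true_ratio
  )
  grid$nmol_qd_per_mg <- expected_amount * rlnorm_cv(nrow(grid), model$noise_cv)

  # total P per mg root (dominated by non-tracer sources)
  grid$total_p_nmol_per_mg <- model$total_p_mean_nmol_per_mg *
    rlnorm_cv(nrow(grid), model$noise_cv / 2)

  # tissue masses (established roots planted 6 weeks earlier are larger)
  mass_mean <- ifelse(grid$compartment == "established", 60, 20)
  grid$root_mass_mg <- mass_mean * rlnorm_cv(nrow(grid), model$noise_cv)
  grid$hyphal_mass_mg <- 5 * rlnorm_cv(nrow(grid), model$noise_cv)

  # per-biovolume concentrations for the retention (hyphae/root) ratio
  true_retention <- rep(model$hyphal_retention_control, nrow(grid))
  ret_cell <- late_lowp & grid$compartment == "young"
  true_retention[ret_cell] <- model$hyphal_retention_lowP_young_late
  root_conc_expected <- 2.0 # nmol per L biovolume, arbitrary realistic scale
  grid$root_conc_per_biovolume <- root_conc_expected *
    rlnorm_cv(nrow(grid), model$noise_cv)
  grid$hyphal_conc_per_biovolume <- root_conc_expected * true_retention *
    rlnorm_cv(nrow(grid), model$noise_cv)

  truth <- data.frame(
    plate_id = grid$plate_id, treatment = grid$treatment,
    compartment = grid$compartment, color = grid$color,
    injection_age_days = grid$injection_age_days,
    expected_nmol_qd_per_mg = expected_amount,
    true_young_established_ratio = true_ratio,
    true_retention_ratio = true_retention,
    stringsAsFactors = FALSE
  )
  cols <- c("plate_id", "treatment", "compartment", "color",
            "injection_age_days", "nmol_qd_per_mg", "total_p_nmol_per_mg",
            "root_mass_mg", "hyphal_mass_mg",
            "hyphal_conc_per_biovolume", "root_conc_per_biovolume")
  structure(
    list(table = grid[, cols], ground_truth = truth, model = model),
    class = "qd_experiment"
  )
}

#' @export
print.qd_experiment <- function(x, ...) {
  cat("Synthetic two-host allocation experiment:",
      nrow(x$table), "records,",
      x$model$n_plates_per_treatment, "plates/treatment, noise CV",
      x$model$noise_cv, ", seed", x$model$seed, "\n")
  invisible(x)
}
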