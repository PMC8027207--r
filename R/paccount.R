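#' QD-apatite to phosphorus conversion
#'
#' Each nmol of QD-apatite carries approximately 700 nmol of phosphorus;
#' the measured stoichiometry used throughout is 708:1.
#'
#' @param nmol_qd nmol of QD-apatite (>= 0, vectorized).
#' @param p_per_qd stoichiometric ratio, default 708.
#' @return nmol P.
#' @export
#' @examples
#' qd_to_p(1) # 708
qd_to_p <- function(nmol_qd, p_per_qd = qd_constants()$p_per_qd) {
  if (any(nmol_qd < 0)) stop("nmol_qd must be nonnegative")
  p_per_qd * nmol_qd
}

#' Percentage of root phosphorus derived from QD-apatite
#'
#' `100 x 708 x nmol_qd_per_mg / total_p_nmol_per_mg`, using the total P
#' content of the root (all sources) as the denominator.
#'
#' @param nmol_qd_per_mg QD-apatite per mg root.
#' @param total_p_nmol_per_mg total P per mg root (> 0).
#' @param p_per_qd stoichiometric ratio, default 708.
#' @return Percent, with attribute `flag_over_100` marking physically
#'   inconsistent inputs (tracer-derived P exceeding total P).
#' @export
percent_p_from_qd <- function(nmol_qd_per_mg, total_p_nmol_per_mg,
                              p_per_qd = qd_constants()$p_per_qd) {
  if (any(total_p_nmol_per_mg <= 0)) stop("total P must be positive")
  pct <- 100 * qd_to_p(nmol_qd_per_mg, p_per_qd) / total_p_nmol_per_mg
  over <- pct > 100
  if (any(over)) {
    warning("QD-derived P exceeds total P for some records (flagged)")
  }
  attr(pct, "flag_over_100") <- over
  pct
}

#' Per-plate young/established allocation ratios
#'
#' For each plate and color, divides the young-root QD amount by the
#' established-root amount of the same plate (the pairing absorbs
#' plate-level multipliers such as extraction efficiency). Plates lacking
#' one member of the pair, or with a zero established amount, are excluded
#' and counted.
#'
#' @param table experiment table (long format, as from
#'   [simulate_experiment()]`$table`): columns `plate_id`, `treatment`,
#'   `compartment`, `color`, `injection_age_days`, `nmol_qd_per_mg`.
#' @return data.frame: `plate_id`, `treatment`, `color`,
#'   `injection_age_days`, `ratio`; attributes `n_excluded_unpaired` and
#'   `n_excluded_zero_denominator`.
#' @export
allocation_ratio <- function(table) {
  need <- c("plate_id", "treatment", "compartment", "color", "nmol_qd_per_mg")
  stopifnot(all(need %in% names(table)))
  if (!"injection_age_days" %in% names(table)) {
    table$injection_age_days <- NA_integer_
  }
  key_all <- paste(table$plate_id, table$color, sep = "\r")
  young <- table[table$compartment == "young", ]
  est <- table[table$compartment == "established", ]
  key_y <- paste(young$plate_id, young$color, sep = "\r")
  key_e <- paste(est$plate_id, est$color, sep = "\r")
  # a pair needs exactly one young and one established record per key
  ok_keys <- intersect(key_y[!duplicated(key_y) & !(key_y %in% key_y[duplicated(key_y)])],
                       key_e[!duplicated(key_e) & !(key_e %in% key_e[duplicated(key_e)])])
  n_unpaired <- length(unique(key_all)) - length(ok_keys)
  young <- young[match(ok_keys, key_y), ]
  est <- est[match(ok_keys, key_e), ]
  zero <- est$nmol_qd_per_mg == 0
  n_zero <- sum(zero)
  out <- data.frame(
    plate_id = young$plate_id[!zero], treatment = young$treatment[!zero],
    color = young$color[!zero],
    injection_age_days = young$injection_age_days[!zero],
    ratio = young$nmol_qd_per_mg[!zero] / est$nmol_qd_per_mg[!zero],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded_unpaired") <- n_unpaired
  attr(out, "n_excluded_zero_denominator") <- n_zero
  out
}

#' Hyphae/root retention ratio per biovolume
#'
#' Ratio of QD-apatite concentration in intraradical hyphae to that in the
#' root cells, both per biovolume (from RICS fits). A value near 1 means
#' equal amounts per biovolume in the two tissue types; smaller values mean
#' more transfer to the root and less hyphal storage. Zero root
#' concentrations are excluded with a flag.
#'
#' @param hyphal_conc_per_biovolume,root_conc_per_biovolume vectors of
#'   per-biovolume concentrations (same units).
#' @return data.frame: `ratio` (NA where excluded), `flag_zero_root`.
#' @export
retention_ratio <- function(hyphal_conc_per_biovolume,
                            root_conc_per_biovolume) {
  stopifnot(length(hyphal_conc_per_biovolume) ==
              length(root_conc_per_biovolume))
  if (any(hyphal_conc_per_biovolume < 0) || any(root_conc_per_biovolume < 0)) {
    stop("concentrations must be nonnegative")
  }
  zero <- root_conc_per_biovolume == 0
  ratio <- ifelse(zero, NA_real_,
                  hyphal_conc_per_biovolume / root_conc_per_biovolume)
  data.frame(ratio = ratio, flag_zero_root = zero)
}

#' Absorbance to phosphorus concentration
#'
#' Converts 880 nm absorbance of the molybdenum-blue assay to P per mg via
#' a supplied standard curve `A = slope x conc + intercept`; negative
#' back-calculated concentrations are floored at zero and flagged.
#'
#' @param absorbance_880nm absorbance values.
#' @param slope,intercept standard curve parameters; slope must be > 0.
#' @return data.frame: `p_conc`, `flag_floored`.
#' @export
absorbance_to_p <- function(absorbance_880nm, slope, intercept = 0) {
  if (slope <= 0) stop("standard-curve slope must be positive")
  conc <- (absorbance_880nm - intercept) / slope
  floored <- conc < 0
  data.frame(p_conc = pmax(conc, 0), flag_floored = floored)
}

#' qPCR Cq to mtDNA copies per mg root
#'
#' Converts quantification-cycle values to target copy numbers through a
#' log-linear standard curve `log10(copies) = slope x Cq + intercept`, with
#' an internal-standard efficiency correction: the same curve form maps the
#' internal standard's observed Cq to observed copies, and the correction
#' factor is `expected_IS_copies / observed_IS_copies`. A missing internal
#' standard yields the uncorrected value with a flag.
#'
#' @param cq_target Cq of the target (R. irregularis mtDNA).
#' @param root_mass_mg root mass used in the extraction (> 0).
#' @param slope,intercept standard curve for log10(copies) vs Cq (slope is
#'   negative for qPCR: more template, earlier Cq). Required configuration;
#'   no published constants are bundled.
#' @param cq_internal_standard Cq of the spiked internal standard, or NA.
#' @param expected_is_copies copies of internal standard spiked in.
#' @return data.frame: `copies_per_mg`, `efficiency_correction`,
#'   `flag_no_internal_standard`.
#' @export
cq_to_copies_per_mg <- function(cq_target, root_mass_mg, slope, intercept,
                                cq_internal_standard = NA_real_,
                                expected_is_copies = NA_real_) {
  if (any(cq_target <= 0)) stop("Cq must be positive")
  if (any(root_mass_mg <= 0)) stop("root mass must be positive")
  copies <- 10^(slope * cq_target + intercept)
  no_is <- is.na(cq_internal_standard)
  corr <- rep(1, length(copies))
  if (any(!no_is)) {
    if (any(!is.na(expected_is_copies) & expected_is_copies <= 0)) {
      stop("expected internal-standard copies must be positive")
    }
    observed_is <- 10^(slope * cq_internal_standard[!no_is] + intercept)
    corr[!no_is] <- expected_is_copies / observed_is
  }
  if (any(no_is)) {
    warning("missing internal-standard Cq; uncorrected values flagged")
  }
  data.frame(copies_per_mg = copies * corr / root_mass_mg,
             efficiency_correction = corr,
             flag_no_internal_standard = no_is)
}

#' Intraradical fungal abundance transform
#'
#' `log10(total root mass x copies per gram)`: the whole-root fungal load
#' on a log scale. Root mass is supplied in mg and converted to g; copies
#' are supplied per mg and converted to per g.
#'
#' @param total_root_mass_mg root mass, mg (> 0).
#' @param copies_per_mg mtDNA copies per mg root; zeros are flagged as
#'   below detection and returned as NA.
#' @return data.frame: `log_abundance`, `flag_below_detection`.
#' @export
#' @examples
#' fungal_abundance_transform(1000, 1e3) # log10(1 g x 1e6 copies/g) = 6
fungal_abundance_transform <- function(total_root_mass_mg, copies_per_mg) {
  if (any(total_root_mass_mg <= 0)) stop("root mass must be positive")
  if (any(copies_per_mg < 0)) stop("copy numbers must be nonnegative")
  below <- copies_per_mg == 0
  mass_g <- total_root_mass_mg / 1000
  copies_per_g <- copies_per_mg * 1000
  la <- ifelse(below, NA_real_, log10(mass_g * copies_per_g))
  data.frame(log_abundance = la, flag_below_detection = below)
}
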