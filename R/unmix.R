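#' Subtract a blank spectrum
#'
#' Elementwise background subtraction with clipping at zero (counts are
#' physical); the number of clipped bins is reported as an attribute.
#'
#' @param spectrum,blank_spectrum `qd_spectrum` objects on the same grid.
#' @return A `qd_spectrum` with attribute `n_clipped`.
#' @export
subtract_background <- function(spectrum, blank_spectrum) {
  stopifnot(inherits(spectrum, "qd_spectrum"),
            inherits(blank_spectrum, "qd_spectrum"))
  if (!identical(spectrum$wavelengths, blank_spectrum$wavelengths)) {
    stop("spectrum and blank are on different wavelength grids")
  }
  d <- spectrum$counts - blank_spectrum$counts
  n_clip <- sum(d < 0)
  out <- emission_spectrum(spectrum$well_id, pmax(d, 0), spectrum$wavelengths)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Local polynomial smoothing to reduce photon-counting noise. Exactly
#' reproduces any polynomial of degree <= `polyorder` (including at the
#' grid ends) and preserves total counts on smooth inputs.
#'
#' @param spectrum a `qd_spectrum`.
#' @param window odd window length in grid points; `window = 1` is the
#'   identity. Must exceed `polyorder` and not exceed the grid length.
#' @param polyorder local polynomial degree (default 3).
#' @return Smoothed `qd_spectrum` (values may dip slightly negative on
#'   noisy edges; they are clipped at zero, consistent with ingest rules).
#' @export
smooth_spectrum <- function(spectrum, window = 9, polyorder = 3) {
  stopifnot(inherits(spectrum, "qd_spectrum"))
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > length(spectrum$counts)) stop("window longer than the grid")
  if (window == 1) return(spectrum)
  sm <- signal::sgolayfilt(spectrum$counts, p = polyorder, n = window)
  emission_spectrum(spectrum$well_id, pmax(sm, 0), spectrum$wavelengths)
}

#' Unmix a spectrum into component loadings
#'
#' Solves `min || y - A c ||^2 subject to c >= 0`, where the columns of `A`
#' are the unit-area reference shapes (autofluorescence plus QD colors).
#' Because the shapes are unit-area, each coefficient is directly the
#' integrated photon count attributed to that component. An unconstrained
#' ordinary least-squares mode is retained as a debugging oracle; for
#' spectra whose nonnegative solution is interior the two coincide.
#'
#' @param spectrum a `qd_spectrum` on the reference grid (background
#'   subtracted).
#' @param refs a [make_reference_spectra()] set.
#' @param method `"nnls"` (default) or `"ols"` (unconstrained oracle mode).
#' @param max_condition reject designs with condition number above this
#'   (default 1e8), naming the most collinear component pair.
#' @return Object of class `qd_unmix`: `well_id`, `coefficients` (named;
#'   nonnegative under nnls), `per_color_counts` (the QD coefficients),
#'   `autofluorescence_counts`, `residual_norm`, `method`.
#' @export
#' @examples
#' refs <- make_reference_spectra()
#' y <- simulate_well_spectrum(c(2e-9, 0, 0), 0, refs, noiseless = TRUE)
#' unmix_spectrum(y, refs)$per_color_counts
unmix_spectrum <- function(spectrum, refs, method = c("nnls", "ols"),
                           max_condition = 1e8) {
  stopifnot(inherits(spectrum, "qd_spectrum"), inherits(refs, "qd_refs"))
  method <- match.arg(method)
  if (!identical(spectrum$wavelengths, refs$wavelengths)) {
    stop("spectrum is not on the reference wavelength grid")
  }
  a <- refs$components
  if (refs$condition_number > max_condition) {
    cors <- stats::cor(a)
    diag(cors) <- 0
    worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "reference design is ill-conditioned (kappa = %.3g); components '%s' and '%s' collide",
      refs$condition_number, colnames(a)[worst[1]], colnames(a)[worst[2]]))
  }
  y <- spectrum$counts
  if (method == "nnls") {
    # solve on a unit scale (the active-set solver is scale sensitive at
    # the very large photon counts of calibration-gain spectra)
    s <- max(y, 1)
    coefs <- pracma::lsqnonneg(a, y / s)$x * s
  } else {
    coefs <- as.numeric(qr.solve(a, y))
  }
  names(coefs) <- colnames(a)
  resid <- y - as.numeric(a %*% coefs)
  structure(
    list(well_id = spectrum$well_id,
         coefficients = coefs,
         per_color_counts = coefs[-1],
         autofluorescence_counts = coefs[[1]],
         residual_norm = sqrt(sum(resid^2)),
         method = method),
    class = "qd_unmix"
  )
}

#' @export
print.qd_unmix <- function(x, ...) {
  cat("Unmixing result, well", x$well_id, "(", x$method, ")\n")
  print(signif(x$coefficients, 5))
  cat("  residual norm:", format(x$residual_norm, digits = 4), "counts\n")
  invisible(x)
}

#' Fit a photon-count calibration line
#'
#' Least-squares line `counts = slope x concentration + intercept` over the
#' calibration dilution series (seven concentrations per color in the
#' standard design). A non-positive slope is refused with a warning flag
#' rather than silently inverted.
#'
#' @param concentrations mM, at least two distinct values.
#' @param integrated_counts integrated photon counts per well.
#' @param force_origin if TRUE fit `counts = slope x concentration`.
#' @param color optional color label carried into the result.
#' @return Object of class `qd_calibration`: `slope` (counts/mM),
#'   `intercept` (counts), `r_squared`, `color`, `flags`.
#' @export
fit_calibration <- function(concentrations, integrated_counts,
                            force_origin = FALSE, color = NA_character_) {
  if (length(concentrations) < 2) stop("need at least two calibration points")
  if (length(concentrations) != length(integrated_counts)) {
    stop("concentrations and counts differ in length")
  }
  if (stats::var(concentrations) == 0) {
    stop("all calibration concentrations are identical")
  }
  if (any(concentrations < 0)) stop("concentrations must be positive")
  fit <- if (force_origin) {
    stats::lm(integrated_counts ~ 0 + concentrations)
  } else {
    stats::lm(integrated_counts ~ concentrations)
  }
  cf <- coef(fit)
  slope <- unname(cf[["concentrations"]])
  intercept <- if (force_origin) 0 else unname(cf[["(Intercept)"]])
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((integrated_counts - mean(integrated_counts))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  flags <- character(0)
  if (slope <= 0) {
    warning("calibration slope is non-positive; curve flagged unusable")
    flags <- c(flags, "nonpositive_slope")
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         concentrations = concentrations,
         integrated_counts = integrated_counts,
         color = color, flags = flags),
    class = "qd_calibration"
  )
}

#' Calibrate a calibration plate end to end
#'
#' Unmixes every well of a [simulate_calibration_plate()] (or equivalent
#' measured plate), integrates the target color's counts and fits the
#' calibration line.
#'
#' @param plate a `qd_calibration_plate`.
#' @param refs reference set containing the plate's color.
#' @param ... passed to [fit_calibration()].
#' @return A `qd_calibration`.
#' @export
calibrate_plate <- function(plate, refs, ...) {
  stopifnot(inherits(plate, "qd_calibration_plate"))
  counts <- vapply(plate$spectra, function(s) {
    unmix_spectrum(s, refs)$per_color_counts[[plate$color]]
  }, numeric(1))
  fit_calibration(plate$concentrations, counts, color = plate$color, ...)
}

#' Convert unmixed counts to nmol QD per mg tissue
#'
#' Back-calculates concentration from the calibration line,
#' `conc_mM = (counts - intercept) / slope`, converts to nmol in the well
#' via the well volume (`tissue_mass_mg x buffer_ul_per_mg` uL; with
#' mM = nmol/uL the product is nmol), and divides by the tissue mass.
#' Negative back-calculated concentrations are floored at zero and flagged.
#'
#' @param result a [unmix_spectrum()] result.
#' @param curves named list of `qd_calibration`, one per QD color present in
#'   `result$per_color_counts`.
#' @param buffer_ul_per_mg assay volume per mg dry tissue (default 150).
#' @param tissue_mass_mg tissue mass in the well (default 1).
#' @param floor_negative floor negative back-calculated concentrations at
#'   zero (default TRUE, amounts are physical). Set FALSE when the signed
#'   estimate distribution matters, as in [detection_limit()] blanks.
#' @return data.frame: `well_id`, `color`, `nmol_per_mg`, `flag_floored`.
#' @export
counts_to_nmol_per_mg <- function(result, curves,
                                  buffer_ul_per_mg = qd_constants()$buffer_ul_per_mg,
                                  tissue_mass_mg = 1,
                                  floor_negative = TRUE) {
  stopifnot(inherits(result, "qd_unmix"))
  if (tissue_mass_mg <= 0) stop("tissue mass must be positive")
  colors <- names(result$per_color_counts)
  missing <- setdiff(colors, names(curves))
  if (length(missing)) {
    stop("missing calibration for color(s): ", paste(missing, collapse = ", "))
  }
  rows <- lapply(colors, function(cl) {
    cu <- curves[[cl]]
    stopifnot(inherits(cu, "qd_calibration"))
    conc <- (result$per_color_counts[[cl]] - cu$intercept) / cu$slope
    floored <- floor_negative && conc < 0
    if (floor_negative) conc <- max(conc, 0)
    nmol <- conc * buffer_ul_per_mg * tissue_mass_mg # mM x uL = nmol
    data.frame(well_id = result$well_id, color = cl,
               nmol_per_mg = nmol / tissue_mass_mg,
               flag_floored = floored, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average replicate wells of one sample
#'
#' Arithmetic per-color mean across the replicate wells of a sample (five
#' wells in the standard plate layout), with SEM and n. Averaging first
#' avoids pseudoreplication in the downstream statistics.
#'
#' @param well_table data.frame from [counts_to_nmol_per_mg()] rows
#'   (columns `well_id`, `color`, `nmol_per_mg`), all wells of one sample.
#' @param sample_id label of the sample; all wells must carry it in a
#'   `sample_id` column if present.
#' @return data.frame: `sample_id`, `color`, `nmol_per_mg` (mean), `sem`,
#'   `n_wells`, `flag_single_well`.
#' @export
average_replicate_wells <- function(well_table, sample_id = "sample") {
  stopifnot(nrow(well_table) >= 1)
  if ("sample_id" %in% names(well_table) &&
      length(unique(well_table$sample_id)) > 1) {
    stop("wells from different samples cannot be averaged together")
  }
  out <- do.call(rbind, lapply(split(well_table, well_table$color), function(d) {
    n <- nrow(d)
    data.frame(sample_id = sample_id, color = d$color[1],
               nmol_per_mg = mean(d$nmol_per_mg),
               sem = if (n >= 2) stats::sd(d$nmol_per_mg) / sqrt(n) else NA_real_,
               n_wells = n, flag_single_well = n == 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detection limit of the unmixing pipeline
#'
#' Three-sigma blank-based limit of detection: the smallest per-mg QD
#' amount whose calibrated estimate exceeds the blank mean plus three blank
#' standard deviations. Since the calibrated estimate is linear in the true
#' amount, that smallest amount equals `3 x sd(blank estimates)` above the
#' blank mean, computed per color and reported in fmol per mg.
#'
#' @param blank_estimates data.frame of calibrated estimates for
#'   autofluorescence-only wells (columns `color`, `nmol_per_mg`), at least
#'   20 per color; typically per-sample values after
#'   [average_replicate_wells()].
#' @return data.frame: `color`, `limit_fmol_per_mg`, `blank_mean_fmol`,
#'   `blank_sd_fmol`, `n_blanks`, `flag_zero_variance`.
#' @export
detection_limit <- function(blank_estimates) {
  stopifnot(all(c("color", "nmol_per_mg") %in% names(blank_estimates)))
  out <- do.call(rbind, lapply(split(blank_estimates, blank_estimates$color),
                               function(d) {
    n <- nrow(d)
    if (n < 20) stop("need at least 20 blank wells per color")
    s <- stats::sd(d$nmol_per_mg)
    zero_var <- s == 0
    if (zero_var) {
      warning("blank ensemble has zero variance; detection limit is 0")
    }
    data.frame(color = d$color[1],
               limit_fmol_per_mg = 3 * s * 1e6, # nmol -> fmol
               blank_mean_fmol = mean(d$nmol_per_mg) * 1e6,
               blank_sd_fmol = s * 1e6,
               n_blanks = n, flag_zero_variance = zero_var,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Quantify a set of sample wells end to end
#'
#' The full plate-reader chain: background subtraction against a blank,
#' unmixing against the reference set, optional Savitzky-Golay smoothing of
#' the reconstructed component curves before integration (the default;
#' smoothing the raw spectrum before unmixing is available via
#' `smooth_stage = "before"`), calibration to nmol, and per-sample
#' averaging over replicate wells.
#'
#' @param spectra list of `qd_spectrum` (replicate wells of one sample).
#' @param refs reference spectra set.
#' @param curves named list of per-color `qd_calibration`.
#' @param blank optional blank `qd_spectrum` to subtract.
#' @param sample_id sample label.
#' @param smooth_stage `"after"` (default: smooth reconstructed component
#'   curves after unmixing), `"before"` (smooth the raw spectrum), or
#'   `"none"`.
#' @param window,polyorder smoothing parameters, see [smooth_spectrum()].
#' @param tissue_mass_mg mass per well, mg.
#' @param buffer_ul_per_mg assay volume per mg.
#' @param floor_negative see [counts_to_nmol_per_mg()].
#' @return data.frame as returned by [average_replicate_wells()].
#' @export
quantify_wells <- function(spectra, refs, curves, blank = NULL,
                           sample_id = "sample",
                           smooth_stage = c("after", "before", "none"),
                           window = 9, polyorder = 3,
                           tissue_mass_mg = 1,
                           buffer_ul_per_mg = qd_constants()$buffer_ul_per_mg,
                           floor_negative = TRUE) {
  smooth_stage <- match.arg(smooth_stage)
  if (inherits(spectra, "qd_spectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    if (!is.null(blank)) s <- subtract_background(s, blank)
    if (smooth_stage == "before") s <- smooth_spectrum(s, window, polyorder)
    u <- unmix_spectrum(s, refs)
    if (smooth_stage == "after") {
      # reconstruct each QD component, smooth it, and re-integrate; the
      # shapes are analytic so this is a near-identity that mirrors the
      # smooth-after-unmix processing order
      for (cl in names(u$per_color_counts)) {
        comp <- u$coefficients[[cl]] * refs$components[, cl]
        sm <- smooth_spectrum(emission_spectrum(s$well_id, pmax(comp, 0),
                                                refs$wavelengths),
                              window, polyorder)
        u$per_color_counts[[cl]] <- sum(sm$counts)
      }
    }
    counts_to_nmol_per_mg(u, curves, buffer_ul_per_mg, tissue_mass_mg,
                          floor_negative = floor_negative)
  })
  average_replicate_wells(do.call(rbind, rows), sample_id = sample_id)
}
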