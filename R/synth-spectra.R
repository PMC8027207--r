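#' Simulate one well's emission spectrum
#'
#' Generates the photon counts a plate reader would record for a well
#' containing known nmol amounts of each QD color plus tissue
#' autofluorescence. The expected spectrum is the linear mixture
#' `sum_i amount_i * brightness_i * shape_i + af_amount * af_shape`;
#' realized counts are Poisson-distributed around it (the plate reader is a
#' photon counter), unless `noiseless = TRUE`.
#'
#' @param amounts named or positional numeric vector, nmol of each QD color,
#'   in the color order of `refs` (excluding autofluorescence). All >= 0.
#' @param autofluorescence_amount total expected autofluorescence counts
#'   (arbitrary units; the autofluorescence reference is unit-area so this is
#'   the integrated count).
#' @param refs a [make_reference_spectra()] set.
#' @param well_id well label carried into the output.
#' @param noiseless if TRUE, return the expected counts exactly (no Poisson
#'   draw); used for identity checks.
#' @param seed optional integer seed for the Poisson draw.
#' @return A `qd_spectrum` with attribute `ground_truth`: list of the true
#'   amounts, autofluorescence, and expected counts.
#' @export
#' @examples
#' refs <- make_reference_spectra()
#' s <- simulate_well_spectrum(c(1, 0, 0), 0, refs, noiseless = TRUE)
#' sum(s$counts) # = 1 nmol x green brightness
simulate_well_spectrum <- function(amounts, autofluorescence_amount, refs,
                                   well_id = "well", noiseless = FALSE,
                                   seed = NULL) {
  ncolors <- ncol(refs$components) - 1L
  if (length(amounts) != ncolors) {
    stop("need one amount per QD color in the reference set")
  }
  if (any(amounts < 0)) stop("amounts must be nonnegative")
  if (autofluorescence_amount < 0) stop("autofluorescence must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  scale <- c(autofluorescence_amount, as.numeric(amounts) * refs$brightness)
  expected <- as.numeric(refs$components %*% scale)
  counts <- if (noiseless) expected else rpois_large(length(expected), expected)
  out <- emission_spectrum(well_id, counts, refs$wavelengths)
  attr(out, "ground_truth") <- list(
    well_id = as.character(well_id),
    amounts_nmol = stats::setNames(as.numeric(amounts),
                                   colnames(refs$components)[-1]),
    autofluorescence = autofluorescence_amount,
    expected_counts = expected
  )
  out
}

#' Simulate a calibration plate for one color
#'
#' One well per concentration of a single QD color, for building the
#' photon-count vs concentration calibration line. The default
#' concentrations are the seven-point dilution series used for each color:
#' 13.1, 9.83, 7.37, 5.53, 4.15, 3.11 and 2.33 mM. Expected integrated
#' counts are proportional to concentration
#' (`conc_mM x well_volume_ul` nmol in the well, times the color's
#' brightness).
#'
#' @param color a [qd_color()].
#' @param concentrations mM, positive (a zero is allowed and yields a blank).
#' @param refs reference set containing the color (for shape and grid); built
#'   from the single color if NULL.
#' @param well_volume_ul calibration well volume in uL; with mM = nmol/uL the
#'   amount in a well is `conc * well_volume_ul` nmol. Default 150.
#' @param autofluorescence_amount blank-level autofluorescence counts added
#'   to every well (default 0: calibration standards are tissue-free).
#' @param noiseless skip the Poisson draw.
#' @param seed integer seed.
#' @return List of class `qd_calibration_plate`: `color`, `concentrations`,
#'   `spectra` (list of `qd_spectrum`), `well_volume_ul`.
#' @export
simulate_calibration_plate <- function(color,
                                       concentrations = c(13.1, 9.83, 7.37,
                                                          5.53, 4.15, 3.11, 2.33),
                                       refs = NULL,
                                       well_volume_ul = 150,
                                       autofluorescence_amount = 0,
                                       noiseless = FALSE, seed = NULL) {
  if (length(concentrations) == 0L) stop("need at least one concentration")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (is.null(refs)) refs <- make_reference_spectra(list(color))
  if (!color$name %in% colnames(refs$components)) {
    stop("reference set does not contain color ", color$name)
  }
  if (!is.null(seed)) set.seed(seed)
  ncolors <- ncol(refs$components) - 1L
  idx <- match(color$name, colnames(refs$components)[-1])
  spectra <- lapply(seq_along(concentrations), function(i) {
    amounts <- numeric(ncolors)
    amounts[idx] <- concentrations[i] * well_volume_ul # nmol in well
    simulate_well_spectrum(amounts, autofluorescence_amount, refs,
                           well_id = sprintf("%s_cal_%02d", color$name, i),
                           noiseless = noiseless)
  })
  structure(
    list(color = color$name, concentrations = concentrations,
         spectra = spectra, well_volume_ul = well_volume_ul),
    class = "qd_calibration_plate"
  )
}
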