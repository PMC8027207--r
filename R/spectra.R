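#' Describe a QD color channel
#'
#' A QD color is characterized by its emission peak, its full width at half
#' maximum, and its brightness: the total integrated photon count per nmol of
#' QD-apatite at the calibration acquisition gain. The three tracer colors
#' used in the two-host experiment peak at 488 nm (green, injected 21 days
#' before harvest), 572 nm (yellow, 14 days) and 666 nm (red, 7 days).
#'
#' @param name label, one of "green", "yellow", "red" (or any unique label).
#' @param peak_wavelength emission maximum in nm; must lie on the 450-800 nm
#'   acquisition window.
#' @param fwhm full width at half maximum in nm (> 0). CdSeS/ZnS dots are
#'   narrow emitters; 30 nm is typical.
#' @param brightness integrated photon counts per nmol QD at calibration gain.
#' @return An object of class `qd_color`.
#' @export
#' @examples
#' qd_color("green", 488)
qd_color <- function(name, peak_wavelength, fwhm = 30,
                     brightness = 5e9) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (peak_wavelength < 450 || peak_wavelength > 800) {
    stop("peak_wavelength must lie within the 450-800 nm acquisition window")
  }
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (brightness <= 0) stop("brightness must be > 0")
  structure(
    list(name = name, peak_wavelength = peak_wavelength,
         fwhm = fwhm, brightness = brightness),
    class = "qd_color"
  )
}

#' Default tracer color set
#'
#' The three injection colors with their emission peaks, in injection order
#' (green first, red last).
#'
#' @param brightness integrated counts per nmol at calibration gain, shared by
#'   all colors (each color has the same particle size and surface chemistry).
#' @return List of three `qd_color` objects named green, yellow, red.
#' @export
default_qd_colors <- function(brightness = 5e9) {
  list(
    green  = qd_color("green", 488, 30, brightness),
    yellow = qd_color("yellow", 572, 30, brightness),
    red    = qd_color("red", 666, 30, brightness)
  )
}

# Gaussian emission shape on the grid, unit area (sums to 1 over bins).
gaussian_shape <- function(wl, peak, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  s <- exp(-(wl - peak)^2 / (2 * sigma^2))
  s / sum(s)
}

# Broad autofluorescence shape: log-normal in wavelength, peaking near
# `peak` nm. sdlog controls the width/asymmetry of the long red tail.
autofluorescence_shape <- function(wl, peak = 520, sdlog = 0.22) {
  # mode of a lognormal density in x = wl - 400 is exp(mu - sdlog^2)
  x <- wl - 400
  mu <- log(peak - 400) + sdlog^2
  s <- ifelse(x > 0, exp(-(log(x) - mu)^2 / (2 * sdlog^2)) / x, 0)
  if (sum(s) <= 0) stop("degenerate autofluorescence shape")
  s / sum(s)
}

#' Build the reference spectra set used for unmixing
#'
#' Constructs the design matrix of spectral unmixing: one unit-area,
#' nonnegative emission shape per component on the fixed 450-800 nm grid.
#' Components are ordered autofluorescence first, then the QD colors in the
#' order given. QD shapes are Gaussian; the autofluorescence reference is a
#' broad log-normal-shaped curve.
#'
#' @param colors list of [qd_color()] objects with distinct peaks.
#' @param af_peak autofluorescence peak wavelength, nm.
#' @param af_sdlog autofluorescence log-width (dimensionless).
#' @return Object of class `qd_refs`: list with `wavelengths` (the grid),
#'   `components` (176 x K matrix, unit-area columns; column 1 is
#'   autofluorescence), `brightness` (named counts/nmol per color) and
#'   `condition_number` of the design matrix.
#' @export
#' @examples
#' refs <- make_reference_spectra(default_qd_colors())
#' colSums(refs$components)
make_reference_spectra <- function(colors = default_qd_colors(),
                                   af_peak = 520, af_sdlog = 0.22) {
  stopifnot(length(colors) >= 1L)
  peaks <- vapply(colors, function(cc) cc$peak_wavelength, numeric(1))
  if (anyDuplicated(peaks)) {
    stop("QD colors must have distinct emission peaks")
  }
  wl <- wavelength_grid()
  shapes <- vapply(colors, function(cc) gaussian_shape(wl, cc$peak_wavelength, cc$fwhm),
                   numeric(length(wl)))
  af <- autofluorescence_shape(wl, af_peak, af_sdlog)
  components <- cbind(autofluorescence = af, shapes)
  colnames(components) <- c("autofluorescence",
                            unname(vapply(colors, function(cc) cc$name,
                                          character(1))))
  if (any(components < 0)) stop("reference shapes must be nonnegative")
  structure(
    list(
      wavelengths = wl,
      components = components,
      brightness = stats::setNames(
        vapply(colors, function(cc) cc$brightness, numeric(1)),
        vapply(colors, function(cc) cc$name, character(1))
      ),
      condition_number = kappa(components, exact = TRUE)
    ),
    class = "qd_refs"
  )
}

#' @export
print.qd_refs <- function(x, ...) {
  cat("Reference spectra set:", ncol(x$components), "components on",
      length(x$wavelengths), "wavelengths (",
      min(x$wavelengths), "-", max(x$wavelengths), "nm )\n")
  cat("  components:", paste(colnames(x$components), collapse = ", "), "\n")
  cat("  design condition number:", format(x$condition_number, digits = 4), "\n")
  invisible(x)
}

#' Construct an emission spectrum
#'
#' One well's photon counts on the fixed wavelength grid.
#'
#' @param well_id well label.
#' @param counts numeric vector of photon counts, length 176, nonnegative.
#' @param wavelengths the grid; defaults to [wavelength_grid()].
#' @return Object of class `qd_spectrum`.
#' @export
emission_spectrum <- function(well_id, counts, wavelengths = wavelength_grid()) {
  if (length(counts) != length(wavelengths)) {
    stop("counts must have one value per grid wavelength")
  }
  if (length(wavelengths) != 176L || wavelengths[1] != 450 || wavelengths[176] != 800) {
    stop("wavelength grid must be 450-800 nm in 2 nm steps (176 points)")
  }
  if (any(counts < 0)) stop("counts must be nonnegative on ingest")
  structure(
    list(well_id = as.character(well_id), wavelengths = wavelengths,
         counts = as.numeric(counts)),
    class = "qd_spectrum"
  )
}

#' @export
print.qd_spectrum <- function(x, ...) {
  cat("Emission spectrum, well", x$well_id, ": total",
      format(sum(x$counts), digits = 6), "counts over",
      length(x$wavelengths), "bins\n")
  invisible(x)
}

# Poisson draws that stay usable at the very large expected counts produced
# by calibration-gain simulation: exact below 1e7, Gaussian approximation
# (relative error < 1e-3) above.
rpois_large <- function(n, lambda) {
  out <- numeric(n)
  big <- lambda > 1e7
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) {
    out[big] <- round(stats::rnorm(sum(big), lambda[big], sqrt(lambda[big])))
  }
  pmax(out, 0)
}
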