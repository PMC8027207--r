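#' Stoichiometric and culture-medium constants for the QD-apatite system
#'
#' Fixed quantities of the tracer chemistry and the in vitro culture system.
#' The conjugation chemistry binds approximately 700 phosphorus atoms per
#' quantum dot; the working value used throughout is the measured 708:1
#' nmol P : nmol QD ratio. The working QD-apatite solution is diluted to
#' 228.7 nmol P per mL, and each injection event delivers 1 mL of it.
#' Modified Strullu-Romand (MSR) medium carries 228.7 umol P per L; the
#' phosphorus-limited medium contains 1 percent of that.
#'
#' @param p_per_qd nmol P per nmol QD-apatite. Default 708, the measured
#'   stoichiometry; override for other conjugation chemistries.
#' @return A named list of constants:
#' \describe{
#'   \item{p_per_qd}{nmol P per nmol QD (708).}
#'   \item{working_solution_nmol_p_per_ml}{P concentration of the injected
#'     QD-apatite working solution, nmol/mL (228.7).}
#'   \item{injection_volume_ml}{volume per injection event, mL (1).}
#'   \item{injection_nmol_p}{nmol P delivered per injection event.}
#'   \item{msr_standard_p_umol_per_l}{standard MSR medium P, umol/L (228.7).}
#'   \item{lowp_fraction}{fraction of standard P in the low-P medium (0.01).}
#'   \item{msr_lowp_p_umol_per_l}{low-P MSR medium P, umol/L.}
#'   \item{buffer_ul_per_mg}{borate buffer volume per mg dry root in the
#'     plate-reader assay, uL/mg (150).}
#' }
#' @export
#' @examples
#' qd_constants()$p_per_qd
qd_constants <- function(p_per_qd = 708) {
  stopifnot(is.numeric(p_per_qd), length(p_per_qd) == 1L, p_per_qd > 0)
  std <- 228.7
  lowp_frac <- 0.01
  list(
    p_per_qd = p_per_qd,
    working_solution_nmol_p_per_ml = 228.7,
    injection_volume_ml = 1,
    injection_nmol_p = 228.7 * 1,
    msr_standard_p_umol_per_l = std,
    lowp_fraction = lowp_frac,
    msr_lowp_p_umol_per_l = std * lowp_frac,
    buffer_ul_per_mg = 150
  )
}

#' The fixed plate-reader wavelength grid
#'
#' Emission spectra are acquired from 450 to 800 nm in 2 nm steps
#' (176 points). Every spectrum and reference shape in the package lives on
#' this grid.
#'
#' @return Numeric vector of wavelengths in nm, length 176.
#' @export
#' @examples
#' length(wavelength_grid())
wavelength_grid <- function() {
  seq(450, 800, by = 2)
}
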