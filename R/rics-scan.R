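#' Raster scan configuration for RICS
#'
#' Geometry and timing of the confocal raster scan, plus the detection PSF.
#' Defaults follow the acquisition used for the hyphae-versus-root
#' measurements: 256 x 256 pixel frames of 16 nm pixels (a 4.096 um wide
#' image), 20 us pixel dwell and 1.25 ms raster line time. The line time is
#' treated as an independent quantity: it is the interval between successive
#' line starts and the clock for particle motion across lines, while the
#' pixel dwell sets the within-line lag scale of the correlation model.
#'
#' PSF waists are not part of the acquisition metadata; the defaults
#' (w0 = 0.25 um, wz = 3 w0) are typical for a high-NA water objective and
#' are always overridable.
#'
#' @param pixel_size_nm pixel size in nm (default 16).
#' @param frame_size pixels per side of the square frame (default 256).
#' @param pixel_dwell_us pixel dwell time, us (default 20).
#' @param line_time_ms raster line time, ms (default 1.25).
#' @param w0_um lateral 1/e^2 PSF waist, um (default 0.25).
#' @param wz_um axial waist, um (default 3 * w0).
#' @param gamma geometry factor of the 3D Gaussian observation volume
#'   (default 2^(-3/2)).
#' @return Object of class `rics_scan_config` with derived fields
#'   `image_width_um` (= pixel_size x frame_size) and `focal_volume_um3`
#'   (= pi^(3/2) w0^2 wz).
#' @export
#' @examples
#' rics_scan_config()$image_width_um # 4.096
rics_scan_config <- function(pixel_size_nm = 16, frame_size = 256,
                             pixel_dwell_us = 20, line_time_ms = 1.25,
                             w0_um = 0.25, wz_um = 3 * w0_um,
                             gamma = 2^(-3 / 2)) {
  vals <- c(pixel_size_nm, frame_size, pixel_dwell_us, line_time_ms,
            w0_um, wz_um, gamma)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all scan parameters must be positive and finite")
  }
  structure(
    list(pixel_size_nm = pixel_size_nm,
         frame_size = as.integer(frame_size),
         pixel_dwell_us = pixel_dwell_us,
         line_time_ms = line_time_ms,
         w0_um = w0_um, wz_um = wz_um, gamma = gamma,
         image_width_um = pixel_size_nm * frame_size / 1000,
         focal_volume_um3 = pi^(3 / 2) * w0_um^2 * wz_um),
    class = "rics_scan_config"
  )
}

#' @export
print.rics_scan_config <- function(x, ...) {
  cat(sprintf(
    "RICS scan: %d x %d px of %g nm (%.3f um), dwell %g us, line %g ms\n",
    x$frame_size, x$frame_size, x$pixel_size_nm, x$image_width_um,
    x$pixel_dwell_us, x$line_time_ms))
  cat(sprintf("  PSF w0 = %g um, wz = %g um, gamma = %.4f, Veff = %.4f um^3\n",
              x$w0_um, x$wz_um, x$gamma, x$focal_volume_um3))
  invisible(x)
}

#' Effective focal (observation) volume
#'
#' `V_eff = pi^(3/2) w0^2 wz` for a 3D Gaussian PSF, in um^3.
#'
#' @param scan a [rics_scan_config()].
#' @return Volume in um^3.
#' @export
focal_volume <- function(scan) {
  stopifnot(inherits(scan, "rics_scan_config"))
  scan$focal_volume_um3
}
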