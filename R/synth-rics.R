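#' Simulate a raster-scanned image series of diffusing QD particles
#'
#' Brownian particles in a periodic 3D box are observed through a 3D
#' Gaussian PSF while a raster scan sweeps the focal plane, so that particle
#' motion occurs during the scan. Positions advance by Euler-Maruyama steps
#' on the raster-line clock (`substeps_per_line` updates per line; the
#' default 1 updates once per line, adequate because the rms motion within
#' one line is well below the PSF waist at the default timing). Pixel counts
#' are Poisson draws around `brightness x PSF + offset`.
#'
#' The box must be at least 4 PSF waists wide in every dimension; laterally
#' it is never smaller than the scanned field. The ground truth records the
#' `N` that the correlation amplitude reports, `G0 = gamma / N`: for a 3D
#' Gaussian PSF the zero-lag amplitude is exactly `1 / (c V_psf)` with
#' `V_psf = pi^(3/2) w0^2 wz`, so
#' `N = n_particles * gamma * V_psf / V_box` — the mean particle count in
#' the gamma-weighted observation volume.
#'
#' @param scan a [rics_scan_config()].
#' @param n_particles number of particles in the periodic box (>= 0).
#' @param diffusion_coeff diffusion coefficient, um^2/s (>= 0).
#' @param brightness expected counts per pixel dwell for a particle at the
#'   beam center (default 10).
#' @param n_frames frames to record (default 50).
#' @param seed integer seed.
#' @param offset constant background counts per pixel (default 1).
#' @param box_z_um axial box size, um; default 4 x wz.
#' @param box_xy_um lateral box size, um; default the larger of the scanned
#'   field and 4 x w0.
#' @param substeps_per_line Brownian updates per raster line (default 1;
#'   increase for fine-time oracle runs on small frames).
#' @param positions optional n x 3 matrix of initial positions (um, box
#'   coordinates); default uniform. The scanned field is centered in the
#'   box and the focal plane sits at z = box_z/2.
#' @param noiseless if TRUE, return expected intensities without the
#'   Poisson draw.
#' @return Object of class `qd_rics_series`: list with `frames` (list of
#'   frame matrices, rows = scan lines), `scan`, and `ground_truth`
#'   (n_particles, N in focal volume, D, brightness, offset, box).
#' @export
simulate_rics_image_series <- function(scan = rics_scan_config(),
                                       n_particles, diffusion_coeff,
                                       brightness = 10, n_frames = 50,
                                       seed = NULL, offset = 1,
                                       box_z_um = 4 * scan$wz_um,
                                       box_xy_um = max(scan$image_width_um,
                                                       4 * scan$w0_um),
                                       substeps_per_line = 1L,
                                       positions = NULL,
                                       noiseless = FALSE) {
  stopifnot(inherits(scan, "rics_scan_config"))
  if (n_particles < 0) stop("n_particles must be >= 0")
  if (diffusion_coeff < 0) stop("diffusion_coeff must be >= 0")
  if (box_xy_um < 4 * scan$w0_um || box_z_um < 4 * scan$wz_um) {
    stop("simulation box must be at least 4 PSF waists in each dimension")
  }
  if (box_xy_um < scan$image_width_um) {
    stop("lateral box cannot be smaller than the scanned field")
  }
  if (!is.null(seed)) set.seed(seed)
  nx <- scan$frame_size
  ny <- scan$frame_size
  if (is.null(positions)) {
    positions <- cbind(stats::runif(n_particles, 0, box_xy_um),
                       stats::runif(n_particles, 0, box_xy_um),
                       stats::runif(n_particles, 0, box_z_um))
  } else {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == n_particles, ncol(positions) == 3)
    storage.mode(positions) <- "double"
  }
  line_s <- scan$line_time_ms / 1000
  step_sd <- sqrt(2 * diffusion_coeff * line_s / substeps_per_line)
  raw <- cpp_scan_brownian(
    nx, ny, as.integer(n_frames), scan$pixel_size_nm / 1000,
    positions, step_sd, as.integer(substeps_per_line),
    brightness, offset, scan$w0_um, scan$wz_um,
    box_xy_um, box_xy_um, box_z_um,
    cutoff_xy = 3 * scan$w0_um, cutoff_z = 3 * scan$wz_um,
    add_noise = !noiseless
  )
  frames <- lapply(seq_len(n_frames), function(f) {
    matrix(raw[((f - 1) * nx * ny + 1):(f * nx * ny)],
           nrow = ny, ncol = nx, byrow = TRUE)
  })
  v_box <- box_xy_um^2 * box_z_um
  structure(
    list(frames = frames, scan = scan,
         ground_truth = list(
           n_particles = n_particles,
           N_focal = n_particles * scan$gamma * scan$focal_volume_um3 / v_box,
           D_um2_s = diffusion_coeff,
           brightness = brightness, offset = offset,
           box_um = c(box_xy_um, box_xy_um, box_z_um),
           seed = seed)),
    class = "qd_rics_series"
  )
}

#' Particles in the box needed for a target focal-volume N
#'
#' Convenience inverse of the ground-truth relation
#' `N = n_particles * gamma * V_psf / V_box` (see
#' [simulate_rics_image_series()]).
#'
#' @param N_focal target mean particle number in the gamma-weighted
#'   observation volume (the `N` reported by [fit_diffusion_model()]).
#' @param scan a [rics_scan_config()].
#' @param box_z_um,box_xy_um box dimensions as in
#'   [simulate_rics_image_series()].
#' @return Integer particle count.
#' @export
particles_for_focal_n <- function(N_focal, scan = rics_scan_config(),
                                  box_z_um = 4 * scan$wz_um,
                                  box_xy_um = max(scan$image_width_um,
                                                  4 * scan$w0_um)) {
  round(N_focal * box_xy_um^2 * box_z_um /
          (scan$gamma * scan$focal_volume_um3))
}
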