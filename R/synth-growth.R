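#' Simulate a time-lapse root-growth image series
#'
#' Each frame shows a filled root disk of the prescribed radius centered on
#' a circular gel area, with background speckle noise, emulating dark-field
#' plate imaging (roots brighter than gel). The radius trajectory must be
#' nondecreasing and stay inside the gel.
#'
#' @param radius_trajectory_mm nondecreasing vector of disk radii, mm.
#' @param timestamps_h timestamps in hours (default 2 h cadence).
#' @param image_size pixels per side (default 128).
#' @param mm_per_pixel pixel scale (default 0.7, a 9 cm dish on a 128 px
#'   frame).
#' @param gel_radius_mm radius of the circular gel mask (default 42 mm).
#' @param root_level,background_level mean intensities of root and gel.
#' @param noise_sd Gaussian speckle noise sd.
#' @param seed integer seed.
#' @return Object of class `qd_growth_series`: `frames` (list of
#'   matrices), `timestamps_h`, `gel_mask`, `mm_per_pixel`, and
#'   `ground_truth` (radii and analytic disk areas in mm^2).
#' @export
simulate_growth_series <- function(radius_trajectory_mm,
                                   timestamps_h = 2 * (seq_along(radius_trajectory_mm) - 1),
                                   image_size = 128, mm_per_pixel = 0.7,
                                   gel_radius_mm = 42,
                                   root_level = 0.8, background_level = 0.2,
                                   noise_sd = 0.03, seed = NULL) {
  if (length(radius_trajectory_mm) == 0) stop("empty radius trajectory")
  if (is.unsorted(radius_trajectory_mm)) {
    stop("radius trajectory must be nondecreasing")
  }
  if (max(radius_trajectory_mm) > gel_radius_mm) {
    stop("root disk cannot exceed the gel area")
  }
  if (!is.null(seed)) set.seed(seed)
  center <- (image_size + 1) / 2
  px <- seq_len(image_size)
  dist_mm <- mm_per_pixel *
    sqrt(outer((px - center)^2, (px - center)^2, "+"))
  gel_mask <- dist_mm <= gel_radius_mm
  frames <- lapply(radius_trajectory_mm, function(r) {
    img <- matrix(background_level, image_size, image_size)
    img[dist_mm <= r] <- root_level
    img + matrix(stats::rnorm(image_size^2, 0, noise_sd),
                 image_size, image_size)
  })
  structure(
    list(frames = frames, timestamps_h = timestamps_h,
         gel_mask = gel_mask, mm_per_pixel = mm_per_pixel,
         ground_truth = list(radius_mm = radius_trajectory_mm,
                             area_mm2 = pi * radius_trajectory_mm^2,
                             seed = seed)),
    class = "qd_growth_series"
  )
}
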