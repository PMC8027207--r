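#' Binarize a plate image into root / background
#'
#' Otsu thresholding restricted to the gel-area histogram, with automatic
#' polarity: after thresholding, the minority class is taken as root
#' (roots cover a small fraction of the gel under dark-field imaging, and
#' the choice is invariant to inverting the intensities). A blank frame
#' (zero variance inside the mask) yields an all-zero mask with a flag.
#'
#' @param frame numeric matrix (grayscale image).
#' @param gel_mask logical matrix of valid gel pixels; default all TRUE.
#' @param method thresholding method; only `"otsu"` is implemented.
#' @return Logical matrix (TRUE = root) with attributes `threshold`,
#'   `polarity` ("bright" or "dark" roots) and `flag_blank`.
#' @export
binarize_frame <- function(frame, gel_mask = NULL, method = "otsu") {
  stopifnot(is.matrix(frame))
  method <- match.arg(method, "otsu")
  if (is.null(gel_mask)) gel_mask <- matrix(TRUE, nrow(frame), ncol(frame))
  stopifnot(identical(dim(frame), dim(gel_mask)))
  vals <- frame[gel_mask]
  rng <- range(vals)
  if (diff(rng) == 0) {
    out <- matrix(FALSE, nrow(frame), ncol(frame))
    attr(out, "threshold") <- NA_real_
    attr(out, "polarity") <- NA_character_
    attr(out, "flag_blank") <- TRUE
    return(out)
  }
  scaled <- (frame - rng[1]) / diff(rng)
  scaled[!gel_mask] <- 0
  thr <- EBImage::otsu(matrix(scaled[gel_mask], ncol = 1), range = c(0, 1))
  above <- scaled > thr & gel_mask
  below <- scaled <= thr & gel_mask
  bright_minority <- sum(above) <= sum(below)
  out <- if (bright_minority) above else below
  attr(out, "threshold") <- rng[1] + thr * diff(rng)
  attr(out, "polarity") <- if (bright_minority) "bright" else "dark"
  attr(out, "flag_blank") <- FALSE
  out
}

#' Root area fraction of the gel
#'
#' Fraction of gel-area pixels flagged as root; root pixels outside the
#' mask are ignored.
#'
#' @param binary logical matrix from [binarize_frame()].
#' @param gel_mask logical matrix of valid gel pixels.
#' @return Fraction in `[0, 1]`.
#' @export
area_fraction <- function(binary, gel_mask) {
  stopifnot(identical(dim(binary), dim(gel_mask)))
  if (!any(gel_mask)) stop("gel mask is empty")
  sum(binary & gel_mask) / sum(gel_mask)
}

#' Root growth rate from an area time series
#'
#' Smooths the area trajectory with a centered moving average (default 12
#' frames, i.e. 24 h at the 2 h imaging cadence) and differentiates it by
#' central differences, giving a rate in mm^2 per hour.
#'
#' @param time_h timestamps in hours, strictly increasing.
#' @param area_mm2 root area at each timestamp, mm^2.
#' @param smooth_window moving-average window in frames (default 12; 1
#'   disables smoothing).
#' @return data.frame: `time_h`, `area_mm2` (smoothed),
#'   `rate_mm2_per_h`; attribute `smooth_window`.
#' @export
growth_rate <- function(time_h, area_mm2, smooth_window = 12) {
  stopifnot(length(time_h) == length(area_mm2))
  if (length(time_h) < 2) stop("need at least two timepoints")
  if (any(duplicated(time_h))) stop("duplicate timestamps")
  if (is.unsorted(time_h, strictly = TRUE)) stop("timestamps must increase")
  n <- length(area_mm2)
  w <- min(smooth_window, n)
  sm <- if (w > 1) {
    half_lo <- floor((w - 1) / 2)
    half_hi <- w - 1 - half_lo
    vapply(seq_len(n), function(i) {
      mean(area_mm2[max(1, i - half_lo):min(n, i + half_hi)])
    }, numeric(1))
  } else area_mm2
  rate <- numeric(n)
  rate[1] <- (sm[2] - sm[1]) / (time_h[2] - time_h[1])
  rate[n] <- (sm[n] - sm[n - 1]) / (time_h[n] - time_h[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    rate[i] <- (sm[i + 1] - sm[i - 1]) / (time_h[i + 1] - time_h[i - 1])
  }
  out <- data.frame(time_h = time_h, area_mm2 = sm, rate_mm2_per_h = rate)
  attr(out, "smooth_window") <- w
  out
}

#' Quantify a growth image series
#'
#' Runs [binarize_frame()], [area_fraction()] and [growth_rate()] over a
#' time-lapse series, converting the area fraction to absolute mm^2 via
#' the pixel scale so that fraction x gel area equals the area fed to the
#' rate estimator.
#'
#' @param series a `qd_growth_series` (see [simulate_growth_series()]) or a
#'   list with `frames`, `timestamps_h`, `gel_mask`, `mm_per_pixel`.
#' @param smooth_window passed to [growth_rate()].
#' @return data.frame: `time_h`, `fraction`, `area_mm2`, `rate_mm2_per_h`.
#' @export
quantify_growth_series <- function(series, smooth_window = 12) {
  frames <- series$frames
  fracs <- vapply(frames, function(f) {
    area_fraction(binarize_frame(f, series$gel_mask), series$gel_mask)
  }, numeric(1))
  gel_area_mm2 <- sum(series$gel_mask) * series$mm_per_pixel^2
  gr <- growth_rate(series$timestamps_h, fracs * gel_area_mm2, smooth_window)
  data.frame(time_h = gr$time_h, fraction = fracs,
             area_mm2 = gr$area_mm2, rate_mm2_per_h = gr$rate_mm2_per_h)
}
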