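#' Moving-average intensity correction
#'
#' Removes slowly varying immobile structure (cell walls, vacuole edges)
#' before correlation analysis: each pixel's sliding temporal mean (a
#' centered window of `window_frames` frames, truncated at the ends of the
#' series) is subtracted and the global stack mean is added back, so the
#' overall mean intensity is preserved exactly.
#'
#' @param frames list of frame matrices (as in a `qd_rics_series`).
#' @param window_frames window length in frames (default 10); `window = 1`
#'   degenerates to replacing every frame by the global mean and warns.
#' @return List of corrected frame matrices.
#' @export
moving_average_correction <- function(frames, window_frames = 10) {
  n <- length(frames)
  if (window_frames < 1 || window_frames > n) {
    stop("window_frames must be between 1 and the number of frames")
  }
  if (window_frames == 1) {
    warning("window of 1 frame removes all fluctuations (degenerate)")
  }
  arr <- simplify2array(frames) # ny x nx x n
  gm <- mean(arr)
  half_lo <- floor((window_frames - 1) / 2)
  half_hi <- window_frames - 1 - half_lo
  # cumulative sum along time for O(n) sliding means
  cs <- array(0, dim = dim(arr) + c(0, 0, 1))
  for (t in seq_len(n)) cs[, , t + 1] <- cs[, , t] + arr[, , t]
  out <- vector("list", n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - half_lo)
    hi <- min(n, t + half_hi)
    ma <- (cs[, , hi + 1] - cs[, , lo]) / (hi - lo + 1)
    out[[t]] <- arr[, , t] - ma
  }
  shift <- gm - mean(simplify2array(out))
  lapply(out, function(m) m + shift)
}

#' Spatial autocorrelation function of a raster image series
#'
#' Computes the RICS ACF
#' `G(xi, psi) = <dI(x, y) dI(x + xi, y + psi)> / <I>^2`
#' with `dI = I - <I>` taken per frame, the average running over all
#' non-wrapping pixel pairs, and the result averaged over frames. The
#' correlation sums are evaluated with zero-padded FFTs; a direct
#' double-loop evaluation on small images is used as the validation oracle
#' in the test suite. The ACF is exactly symmetric under
#' `(xi, psi) -> (-xi, -psi)`.
#'
#' @param frames list of frame matrices (rows = scan lines, columns = fast
#'   scan axis) or a `qd_rics_series`.
#' @param max_xi,max_psi largest lags (pixels) to retain; defaults keep
#'   everything up to frame size - 1.
#' @return Object of class `qd_rics_acf`: `values` (matrix indexed by
#'   psi x xi lags), `xi`, `psi` (lag vectors), `values_sd` (across-frame
#'   standard deviation per lag), `n_frames_averaged`, `mean_intensity`,
#'   and `flag_zero_variance`.
#' @export
compute_acf <- function(frames, max_xi = NULL, max_psi = NULL) {
  if (inherits(frames, "qd_rics_series")) frames <- frames$frames
  stopifnot(length(frames) >= 1)
  ny <- nrow(frames[[1]])
  nx <- ncol(frames[[1]])
  if (is.null(max_xi)) max_xi <- nx - 1L
  if (is.null(max_psi)) max_psi <- ny - 1L
  max_xi <- min(max_xi, nx - 1L)
  max_psi <- min(max_psi, ny - 1L)

  # counts of contributing (non-wrapping) pairs per lag
  xi <- -max_xi:max_xi
  psi <- -max_psi:max_psi
  npairs <- outer(ny - abs(psi), nx - abs(xi))

  per_frame <- lapply(frames, function(fr) {
    mu <- mean(fr)
    if (stats::var(as.numeric(fr)) == 0) return(NULL) # constant frame
    d <- fr - mu
    pad <- matrix(0, 2 * ny, 2 * nx)
    pad[1:ny, 1:nx] <- d
    ft <- stats::fft(pad)
    corr <- Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / (4 * nx * ny)
    # corr[1 + psi mod 2ny, 1 + xi mod 2nx] holds sum_{x,y} d * d(shifted)
    rows <- 1 + (psi %% (2 * ny))
    cols <- 1 + (xi %% (2 * nx))
    corr[rows, cols, drop = FALSE] / npairs / mu^2
  })
  ok <- !vapply(per_frame, is.null, logical(1))
  flag_zero <- any(!ok)
  if (!any(ok)) {
    vals <- matrix(0, length(psi), length(xi))
    sds <- matrix(NA_real_, length(psi), length(xi))
  } else {
    stack <- simplify2array(per_frame[ok])
    if (length(dim(stack)) == 2) stack <- array(stack, c(dim(stack), 1))
    vals <- apply(stack, c(1, 2), mean)
    sds <- if (dim(stack)[3] >= 2) apply(stack, c(1, 2), stats::sd) else
      matrix(NA_real_, length(psi), length(xi))
  }
  dimnames(vals) <- dimnames(sds) <- list(psi = psi, xi = xi)
  structure(
    list(values = vals, xi = xi, psi = psi, values_sd = sds,
         n_frames_averaged = sum(ok),
         mean_intensity = mean(vapply(frames, mean, numeric(1))),
         flag_zero_variance = flag_zero),
    class = "qd_rics_acf"
  )
}

# RICS 3D-diffusion model surface on pixel-lag grids.
# xi, psi in pixels; D um^2/s; G0 amplitude; scan supplies geometry/timing.
rics_model_g <- function(xi, psi, G0, D, scan) {
  tau <- scan$pixel_dwell_us * 1e-6 * abs(xi) +
    scan$line_time_ms * 1e-3 * abs(psi)
  dr2 <- (scan$pixel_size_nm / 1000)^2
  den <- 1 + 4 * D * tau / scan$w0_um^2
  denz <- 1 + 4 * D * tau / scan$wz_um^2
  G0 / den / sqrt(denz) * exp(-dr2 * (xi^2 + psi^2) / scan$w0_um^2 / den)
}

#' Fit the 3D diffusion model to a RICS autocorrelation function
#'
#' Weighted least-squares fit of
#' `G(xi, psi) = G0 (1 + 4 D tau / w0^2)^-1 (1 + 4 D tau / wz^2)^-1/2
#'   exp(-(dr^2 (xi^2 + psi^2) / w0^2) / (1 + 4 D tau / w0^2))`
#' with `tau = dwell |xi| + line_time |psi|` and `dr` the pixel size.
#' The zero lag is excluded (uncorrelated shot noise inflates it). The
#' mean particle number in the focal volume is `N = gamma / G0`.
#'
#' Lags are restricted to `|xi| <= max_xi`, `|psi| <= max_psi` (defaults
#' 32 and 8: the lateral axis carries the fast dwell-time decorrelation).
#' Weights are inverse across-frame variance per lag when the ACF was
#' averaged over at least 10 frames, otherwise unweighted.
#'
#' An additive baseline `G_inf` is fitted alongside `G0` and `D`:
#' per-frame mean subtraction biases the measured ACF downward by a
#' constant of order `G0` times the ratio of the speckle (PSF) area to the
#' frame area — appreciable on small frames — and the baseline term
#' absorbs it.
#'
#' @param acf a [compute_acf()] result.
#' @param scan the [rics_scan_config()] of the acquisition.
#' @param max_xi,max_psi fit-region half-widths in pixels.
#' @param start_D vector of starting diffusion coefficients tried in turn
#'   (um^2/s); the best converged fit is kept.
#' @return Object of class `qd_rics_fit`: `N`, `D_um2_s`, `G0`,
#'   `residual_rms`, `concentration_nmol_per_l`, `flags`, and the `fit`
#'   object.
#' @export
fit_diffusion_model <- function(acf, scan, max_xi = 32, max_psi = 8,
                                start_D = c(0.1, 1, 10)) {
  stopifnot(inherits(acf, "qd_rics_acf"), inherits(scan, "rics_scan_config"))
  if (acf$n_frames_averaged < 10) {
    warning("ACF averaged over fewer than 10 frames; fit may be unstable")
  }
  keep_xi <- abs(acf$xi) <= max_xi
  keep_psi <- abs(acf$psi) <= max_psi
  g <- acf$values[keep_psi, keep_xi, drop = FALSE]
  gs <- acf$values_sd[keep_psi, keep_xi, drop = FALSE]
  grid <- expand.grid(psi = acf$psi[keep_psi], xi = acf$xi[keep_xi])
  grid$g <- as.numeric(g)
  grid$sd <- as.numeric(gs)
  grid <- grid[!(grid$xi == 0 & grid$psi == 0), ]
  use_w <- acf$n_frames_averaged >= 10 && all(is.finite(grid$sd)) &&
    all(grid$sd > 0)
  w <- if (use_w) 1 / grid$sd^2 else rep(1, nrow(grid))

  g0_start <- max(mean(grid$g[abs(grid$xi) <= 1 & abs(grid$psi) <= 1]), 1e-6)
  best <- NULL
  for (d0 in start_D) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        g ~ rics_model_g(xi, psi, G0, D, scan) + G_inf,
        data = grid, weights = w,
        start = list(G0 = g0_start, D = d0, G_inf = 0),
        lower = c(G0 = 0, D = 0, G_inf = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) ||
          sum(stats::resid(fit)^2) < sum(stats::resid(best)^2)) best <- fit
    }
  }
  if (is.null(best)) {
    stop("RICS model fit did not converge for any starting value; residual ",
         "trace of last attempt unavailable")
  }
  cf <- coef(best)
  flags <- character(0)
  D_hat <- cf[["D"]]
  if (D_hat < 0) { # lower bound should prevent this; keep the guard
    D_hat <- 0
    flags <- c(flags, "negative_D_clamped")
  }
  G0 <- cf[["G0"]]
  N <- scan$gamma / G0
  structure(
    list(N = N, D_um2_s = D_hat, G0 = G0, G_inf = cf[["G_inf"]],
         residual_rms = sqrt(mean(stats::resid(best)^2)),
         concentration_nmol_per_l = particles_to_concentration(N, scan),
         flags = flags, fit = best),
    class = "qd_rics_fit"
  )
}

#' @export
print.qd_rics_fit <- function(x, ...) {
  cat(sprintf(
    "RICS fit: N = %.3g, D = %.3g um^2/s, G0 = %.4g, conc = %.4g nmol/L, rms %.2e\n",
    x$N, x$D_um2_s, x$G0, x$concentration_nmol_per_l, x$residual_rms))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a fitted particle number to a concentration per biovolume
#'
#' `C = N / (V_eff N_A)`, reported in nmol per litre of tissue volume, with
#' `V_eff = pi^(3/2) w0^2 wz` the effective focal volume.
#'
#' @param N mean particle number in the focal volume (> 0).
#' @param scan a [rics_scan_config()] (supplies the waists).
#' @return Concentration in nmol per L.
#' @export
#' @examples
#' sc <- rics_scan_config()
#' particles_to_concentration(1, sc)
particles_to_concentration <- function(N, scan) {
  stopifnot(inherits(scan, "rics_scan_config"))
  if (any(N <= 0)) stop("N must be positive")
  if (scan$w0_um <= 0 || scan$wz_um <= 0) stop("PSF waists must be positive")
  v_l <- scan$focal_volume_um3 * 1e-15 # um^3 -> L
  n_a <- 6.02214076e23
  N / (v_l * n_a) * 1e9
}
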