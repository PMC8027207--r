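#' Read and write well spectra as CSV
#'
#' One row per well: a `well_id` column followed by 176 wavelength columns
#' labeled `wl_450` ... `wl_800`.
#'
#' @param spectra list of `qd_spectrum`.
#' @param path CSV file path.
#' @return `write_spectra_csv` returns `path` invisibly;
#'   `read_spectra_csv` returns a list of `qd_spectrum`.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "qd_spectrum")) spectra <- list(spectra)
  wl <- wavelength_grid()
  m <- t(vapply(spectra, function(s) s$counts, numeric(length(wl))))
  df <- data.frame(well_id = vapply(spectra, function(s) s$well_id,
                                    character(1)), m)
  names(df) <- c("well_id", paste0("wl_", wl))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  wl_cols <- grep("^wl_", names(df))
  if (length(wl_cols) != 176) {
    stop("expected 176 wavelength columns (wl_450 ... wl_800)")
  }
  lapply(seq_len(nrow(df)), function(i) {
    emission_spectrum(df$well_id[i], as.numeric(df[i, wl_cols]))
  })
}

#' Read and write a reference spectra set as CSV
#'
#' Long-by-component layout: a `component` column plus one column per
#' wavelength; shapes are re-normalized to unit area on read.
#'
#' @param refs a `qd_refs` set.
#' @param path CSV file path.
#' @param brightness named counts-per-nmol vector to attach on read (the
#'   CSV stores shapes only).
#' @return `write_reference_csv` returns `path` invisibly;
#'   `read_reference_csv` returns a `qd_refs`.
#' @export
write_reference_csv <- function(refs, path) {
  stopifnot(inherits(refs, "qd_refs"))
  df <- data.frame(component = colnames(refs$components),
                   t(refs$components))
  names(df) <- c("component", paste0("wl_", refs$wavelengths))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path, brightness = NULL) {
  df <- utils::read.csv(path, check.names = TRUE)
  wl_cols <- grep("^wl_", names(df))
  comp <- t(as.matrix(df[, wl_cols]))
  comp <- sweep(comp, 2, colSums(comp), "/")
  colnames(comp) <- df$component
  rownames(comp) <- NULL
  if (is.null(brightness)) {
    brightness <- stats::setNames(rep(NA_real_, ncol(comp) - 1),
                                  df$component[-1])
  }
  structure(
    list(wavelengths = wavelength_grid(), components = comp,
         brightness = brightness,
         condition_number = kappa(comp, exact = TRUE)),
    class = "qd_refs"
  )
}

#' Write and read a RICS image series as multi-page TIFF plus YAML sidecar
#'
#' Frames are stored as 16-bit unsigned TIFF pages (counts above 65535 are
#' clipped); the scan configuration and ground truth (when present) go to a
#' YAML sidecar next to the TIFF.
#'
#' @param series a `qd_rics_series`.
#' @param tiff_path output TIFF path; the sidecar is `<path>.yaml`.
#' @return `write_rics_series` returns `tiff_path` invisibly;
#'   `read_rics_series` returns a `qd_rics_series`.
#' @export
write_rics_series <- function(series, tiff_path) {
  stopifnot(inherits(series, "qd_rics_series"))
  pages <- lapply(series$frames, function(f) {
    pmin(pmax(round(f), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16)
  meta <- list(
    scan = series$scan[c("pixel_size_nm", "frame_size", "pixel_dwell_us",
                         "line_time_ms", "w0_um", "wz_um", "gamma")],
    n_frames = length(series$frames),
    ground_truth = series$ground_truth
  )
  yaml::write_yaml(meta, paste0(tiff_path, ".yaml"))
  invisible(tiff_path)
}

#' @rdname write_rics_series
#' @export
read_rics_series <- function(tiff_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = TRUE)
  meta <- yaml::read_yaml(paste0(tiff_path, ".yaml"))
  sc <- meta$scan
  scan <- rics_scan_config(
    pixel_size_nm = sc$pixel_size_nm, frame_size = sc$frame_size,
    pixel_dwell_us = sc$pixel_dwell_us, line_time_ms = sc$line_time_ms,
    w0_um = sc$w0_um, wz_um = sc$wz_um, gamma = sc$gamma
  )
  structure(
    list(frames = lapply(pages, function(p) {
           storage.mode(p) <- "double"
           p
         }),
         scan = scan, ground_truth = meta$ground_truth),
    class = "qd_rics_series"
  )
}

#' Write and read the experiment table (with optional ground truth)
#'
#' Plain long-format CSV; the ground truth, when present, is written next
#' to the table as `<path base>_truth.csv`, keyed by plate, compartment
#' and color.
#'
#' @param experiment a `qd_experiment` (or a bare data.frame table).
#' @param path CSV path for the table.
#' @return `write_experiment_csv` returns `path` invisibly;
#'   `read_experiment_csv` returns a data.frame (with a `ground_truth`
#'   attribute if the sidecar exists).
#' @export
write_experiment_csv <- function(experiment, path) {
  tab <- if (inherits(experiment, "qd_experiment")) experiment$table
         else experiment
  utils::write.csv(tab, path, row.names = FALSE)
  if (inherits(experiment, "qd_experiment")) {
    utils::write.csv(experiment$ground_truth,
                     sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_experiment_csv
#' @export
read_experiment_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  if (file.exists(truth_path)) {
    attr(tab, "ground_truth") <- utils::read.csv(truth_path,
                                                 stringsAsFactors = FALSE)
  }
  tab
}
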