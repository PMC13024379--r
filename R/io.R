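#' Read an 8-bit RGB micrograph
#'
#' Accepts PNG or TIFF (decided by file extension); grayscale files are
#' replicated across the three channels.
#'
#' @param path image file path.
#' @return An [rgb_raster].
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_image_rgb: file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("read_image_rgb: unsupported image format '.%s'", ext),
         call. = FALSE)
  )
  if (length(dim(arr)) == 2) {
    arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  }
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  px <- round(arr * 255)
  storage.mode(px) <- "integer"
  rgb_raster(px)
}

#' Write a grayscale plane or RGB raster as 8-bit PNG
#'
#' @param raster a [gray_raster] or [rgb_raster].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(raster, path) {
  img <- if (inherits(raster, "gray_raster")) {
    raster$pixels / 255
  } else if (inherits(raster, "rgb_raster")) {
    raster$pixels / 255
  } else if (inherits(raster, "binary_mask")) {
    raster$pixels * 1
  } else {
    stop("write_image_png: unsupported raster type", call. = FALSE)
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read a voltage-time trace from CSV
#'
#' Expects a header row with columns `time_s` and `voltage_v`
#' (comma-separated, dot decimal, UTF-8); sampling uniformity is validated
#' on load and malformed cells are reported with their line number.
#'
#' @param path CSV file path.
#' @return A [voltage_trace].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_trace_csv: file not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) {
      stop(sprintf("read_trace_csv: cannot parse %s: %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (!all(c("time_s", "voltage_v") %in% names(df))) {
    stop("read_trace_csv: header must contain columns time_s and voltage_v",
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop(sprintf("read_trace_csv: %s has no data rows", path), call. = FALSE)
  }
  parse_col <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf(
        "read_trace_csv: non-numeric %s value at line %d of %s",
        col, bad[1] + 1L, path), call. = FALSE)  # +1 for the header row
    }
    v
  }
  voltage_trace(parse_col("time_s"), parse_col("voltage_v"))
}

#' Write a voltage-time trace to CSV
#'
#' Numbers are written at full double precision so a write/read round trip
#' is lossless to 1e-12 relative.
#'
#' @param trace a [voltage_trace].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  df <- data.frame(time_s = sprintf("%.17g", trace$times),
                   voltage_v = sprintf("%.17g", trace$voltages))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read labeled threshold-calibration samples from CSV
#'
#' Expects columns `label` (values `bead` or `electrode`) and `gray`
#' (grayscale values 0-255).
#'
#' @param path CSV file path.
#' @return List with numeric vectors `bead` and `electrode`.
#' @export
read_threshold_samples <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_threshold_samples: file not found: %s", path),
         call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!all(c("label", "gray") %in% names(df))) {
    stop("read_threshold_samples: need columns label and gray", call. = FALSE)
  }
  bad <- setdiff(unique(df$label), c("bead", "electrode"))
  if (length(bad) > 0) {
    stop(sprintf("read_threshold_samples: unknown label '%s'", bad[1]),
         call. = FALSE)
  }
  list(bead = df$gray[df$label == "bead"],
       electrode = df$gray[df$label == "electrode"])
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_run_config: file not found: %s", path), call. = FALSE)
  }
  yaml::read_yaml(path)
}

#' Write a metrics report as JSON
#'
#' Numbers are serialized at full double precision; the record carries a
#' `schema_version` field.
#'
#' @param report named list of metrics.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  report$schema_version <- "1"
  report$package_version <- as.character(utils::packageVersion("beadmetrics"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' End-to-end image analysis report
#'
#' Runs the full imaging chain on one micrograph: red-green compositing,
#' percentile contrast stretch, threshold calibration (from a labeled-sample
#' CSV or an explicit model), binarization over the ROI, then coverage, 3x3
#' grid uniformity and the axial coverage profile. Writes a JSON metrics
#' record and a CSV of the profile when `out_dir` is given.
#'
#' @param image an [rgb_raster], or a path readable by [read_image_rgb()].
#' @param roi ROI rectangle `c(row0, col0, height, width)`; default full
#'   image.
#' @param threshold a `threshold_model`, or a path to a labeled-sample CSV
#'   for [calibrate_threshold()].
#' @param n_bins axial profile bin count. Default 40.
#' @param p_low,p_high contrast-stretch percentiles. Defaults 1 and 99.
#' @param out_dir if non-NULL, directory to write `image_metrics.json` and
#'   `axial_profile.csv` into (created if missing).
#' @return The report, a named list: `coverage_pct`, `grid_sd_pct`,
#'   `cell_coverages`, `axial_profile` (data frame), `threshold`, `roi`,
#'   `parameters`.
#' @export
run_image_report <- function(image, roi = NULL, threshold, n_bins = 40,
                             p_low = 1, p_high = 99, out_dir = NULL) {
  if (is.character(image)) image <- read_image_rgb(image)
  if (is.character(threshold)) {
    s <- read_threshold_samples(threshold)
    threshold <- calibrate_threshold(s$bead, s$electrode)
  }
  gray <- enhance_contrast(rg_composite(image), p_low = p_low, p_high = p_high)
  mask <- binarize(gray, threshold, roi = roi)
  unif <- grid_uniformity(mask)
  prof <- axial_profile(mask, n_bins = n_bins)
  report <- list(
    coverage_pct = coverage(mask),
    grid_sd_pct = unif$sd,
    cell_coverages = unif$cell_coverages,
    axial_profile = data.frame(bin_center = prof$bin_centers,
                               coverage_pct = prof$coverages),
    threshold = unclass(threshold),
    roi = mask$roi,
    parameters = list(n_bins = n_bins, p_low = p_low, p_high = p_high,
                      channel_combination = "mean(R,G)")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$axial_profile,
                     file.path(out_dir, "axial_profile.csv"),
                     row.names = FALSE)
    write_metrics(report[setdiff(names(report), "axial_profile")],
                  file.path(out_dir, "image_metrics.json"))
  }
  report
}

#' End-to-end trace analysis report
#'
#' Runs [process_trace()] on a voltage trace (object or CSV path) and
#' reports the window integrals, the background-corrected photon charge and
#' all processing parameters; optionally writes the JSON record.
#'
#' @param trace a [voltage_trace] or a CSV path for [read_trace_csv()].
#' @param model a [log_amp_model].
#' @param out_dir if non-NULL, directory to write `trace_metrics.json` into.
#' @param ... onset and integration options passed to [process_trace()].
#' @return The report, a named list: `s_target`, `s_noise`, `q_photon`,
#'   `t_onset`, `window_len`, `flags`, `parameters`.
#' @export
run_trace_report <- function(trace, model = log_amp_model(), out_dir = NULL,
                             ...) {
  if (is.character(trace)) trace <- read_trace_csv(trace)
  pc <- process_trace(trace, model = model, ...)
  report <- list(
    s_target = pc$s_target,
    s_noise = pc$s_noise,
    q_photon = pc$q_photon,
    t_onset = pc$t_onset,
    window_len = pc$windows$window_len,
    flags = pc$flags,
    parameters = pc$params
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics(report, file.path(out_dir, "trace_metrics.json"))
  }
  report
}
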