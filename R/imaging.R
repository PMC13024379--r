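#' Combine the red and green channels of a micrograph
#'
#' On the working electrode the beads appear yellow-green while the exposed
#' platinum is dark gray; the blue channel carries little bead contrast, so
#' the composite plane is the per-pixel mean of the red and green channels
#' (blue discarded), rounded half-up to the nearest integer.
#'
#' @param image an [rgb_raster].
#' @return A [gray_raster] with `provenance = "composite"` and the same
#'   dimensions as `image`.
#' @examples
#' px <- array(0L, dim = c(3, 3, 3))
#' px[, , 1] <- 100L; px[, , 2] <- 200L; px[, , 3] <- 50L
#' rg_composite(rgb_raster(px))$pixels[1, 1]  # 150
#' @export
rg_composite <- function(image) {
  if (!inherits(image, "rgb_raster")) {
    stop("rg_composite: input must be an rgb_raster", call. = FALSE)
  }
  comp <- floor((image$pixels[, , 1] + image$pixels[, , 2]) / 2 + 0.5)
  storage.mode(comp) <- "integer"
  gray_raster(comp, provenance = "composite")
}

#' Percentile linear contrast stretch
#'
#' Maps the `p_low` percentile of the grayscale histogram to 0 and the
#' `p_high` percentile to 255, linearly in between and clipping outside.
#' Percentile anchors (rather than min/max) make the stretch robust to hot
#' pixels. A constant image (coincident percentiles) is returned unchanged.
#'
#' @param gray a [gray_raster].
#' @param p_low,p_high anchor percentiles, `0 <= p_low < p_high <= 100`.
#'   Defaults 1 and 99.
#' @return A [gray_raster] with `provenance = "enhanced"`.
#' @export
enhance_contrast <- function(gray, p_low = 1, p_high = 99) {
  if (!inherits(gray, "gray_raster")) {
    stop("enhance_contrast: input must be a gray_raster", call. = FALSE)
  }
  if (!(p_low >= 0 && p_high <= 100 && p_low < p_high)) {
    stop("enhance_contrast: need 0 <= p_low < p_high <= 100", call. = FALSE)
  }
  q <- stats::quantile(as.vector(gray$pixels), probs = c(p_low, p_high) / 100,
                       names = FALSE)
  if (q[1] == q[2]) {
    return(gray_raster(gray$pixels, provenance = "enhanced"))
  }
  stretched <- floor(255 * (gray$pixels - q[1]) / (q[2] - q[1]) + 0.5)
  stretched <- pmin(pmax(stretched, 0), 255)
  storage.mode(stretched) <- "integer"
  gray_raster(stretched, provenance = "enhanced")
}

#' Calibrate the bead/electrode binarization threshold from labeled samples
#'
#' Grayscale values sampled inside the microchannel are labeled by eye as
#' bead or exposed electrode; the classification threshold is the midpoint of
#' the two class means. The returned model records the class means, counts,
#' and which class is the brighter one.
#'
#' @param bead_samples,electrode_samples non-empty numeric vectors of
#'   grayscale values in 0-255.
#' @return A `threshold_model` with fields `bead_level`, `electrode_level`,
#'   `threshold`, `n_bead`, `n_electrode`.
#' @examples
#' m <- calibrate_threshold(c(180, 190, 200), c(40, 50, 60))
#' m$threshold  # 120
#' @export
calibrate_threshold <- function(bead_samples, electrode_samples) {
  if (length(bead_samples) == 0 || length(electrode_samples) == 0) {
    stop("calibrate_threshold: both classes need at least one sample",
         call. = FALSE)
  }
  if (anyNA(bead_samples) || anyNA(electrode_samples)) {
    stop("calibrate_threshold: NA samples not allowed", call. = FALSE)
  }
  bead_level <- mean(bead_samples)
  electrode_level <- mean(electrode_samples)
  if (bead_level == electrode_level) {
    stop("calibrate_threshold: class means are equal; classes not separable",
         call. = FALSE)
  }
  threshold_model(
    threshold = (bead_level + electrode_level) / 2,
    bead_level = bead_level, electrode_level = electrode_level,
    n_bead = length(bead_samples), n_electrode = length(electrode_samples)
  )
}

#' Construct a threshold model directly
#'
#' Used by [calibrate_threshold()] and available for supplying an explicit
#' threshold (e.g. from a run configuration) without labeled samples.
#'
#' @param threshold grayscale cut, strictly between the two class levels.
#' @param bead_level,electrode_level class mean grayscale values; must differ.
#' @param n_bead,n_electrode sample counts behind each class mean.
#' @return A `threshold_model` object.
#' @export
threshold_model <- function(threshold, bead_level, electrode_level,
                            n_bead = 1L, n_electrode = 1L) {
  if (bead_level == electrode_level) {
    stop("threshold_model: class levels must differ", call. = FALSE)
  }
  lo <- min(bead_level, electrode_level)
  hi <- max(bead_level, electrode_level)
  if (!(threshold > lo && threshold < hi)) {
    stop("threshold_model: threshold must lie strictly between class levels",
         call. = FALSE)
  }
  structure(
    list(threshold = threshold, bead_level = bead_level,
         electrode_level = electrode_level,
         n_bead = as.integer(n_bead), n_electrode = as.integer(n_electrode)),
    class = "threshold_model"
  )
}

#' Binarize a grayscale plane into a bead mask
#'
#' A pixel is labeled bead when its value lies on the bead side of the
#' calibrated threshold: `>= threshold` when the bead class is brighter than
#' the electrode class, `<= threshold` otherwise. White (TRUE) pixels are
#' beads, black (FALSE) pixels are exposed working electrode.
#'
#' @param gray a [gray_raster].
#' @param model a `threshold_model` from [calibrate_threshold()].
#' @param roi region of interest `c(row0, col0, height, width)` (0-based,
#'   half-open); defaults to the full plane. Coverage statistics downstream
#'   are computed within this rectangle.
#' @return A [binary_mask].
#' @export
binarize <- function(gray, model, roi = NULL) {
  if (!inherits(gray, "gray_raster")) {
    stop("binarize: input must be a gray_raster", call. = FALSE)
  }
  if (!inherits(model, "threshold_model")) {
    stop("binarize: model must be a threshold_model", call. = FALSE)
  }
  bead <- if (model$bead_level > model$electrode_level) {
    gray$pixels >= model$threshold
  } else {
    gray$pixels <= model$threshold
  }
  binary_mask(bead, roi = roi)
}

#' Bead coverage of the region of interest
#'
#' Coverage is the bead area fraction `C = S_mb / S_base * 100`, with `S_mb`
#' the bead (white) pixel count and `S_base` the total pixel count of the
#' region.
#'
#' @param mask a [binary_mask].
#' @return Coverage in percent, a number in `[0, 100]`.
#' @export
coverage <- function(mask) {
  if (!inherits(mask, "binary_mask")) {
    stop("coverage: input must be a binary_mask", call. = FALSE)
  }
  px <- roi_pixels(mask)
  if (length(px) == 0) stop("coverage: zero-pixel ROI", call. = FALSE)
  100 * sum(px) / length(px)
}

#' 3x3 grid uniformity statistic
#'
#' The ROI is partitioned into nine equally sized rectangular sub-areas in a
#' 3x3 grid (trimming bottom/outlet-side rows and columns when the dimensions
#' are not divisible by 3, so the cells stay exactly equal), coverage is
#' computed per cell, and the population standard deviation (divisor 9) of
#' the nine cell coverages is the uniformity metric: smaller SD means more
#' uniform bead deposition.
#'
#' @param mask a [binary_mask] whose ROI is at least 3x3.
#' @return A `grid_uniformity` object with `cell_coverages` (9 percentages,
#'   row-major), `sd` (population SD, percent) and `mean_coverage` (percent).
#' @export
grid_uniformity <- function(mask) {
  if (!inherits(mask, "binary_mask")) {
    stop("grid_uniformity: input must be a binary_mask", call. = FALSE)
  }
  px <- roi_pixels(mask)
  h <- nrow(px); w <- ncol(px)
  if (h < 3 || w < 3) {
    stop("grid_uniformity: ROI must be at least 3x3 pixels", call. = FALSE)
  }
  ch <- h %/% 3L; cw <- w %/% 3L
  cells <- numeric(9)
  for (i in 0:2) {
    for (j in 0:2) {
      cell <- px[(i * ch + 1):((i + 1) * ch), (j * cw + 1):((j + 1) * cw)]
      cells[i * 3 + j + 1] <- 100 * sum(cell) / length(cell)
    }
  }
  m <- mean(cells)
  structure(
    list(cell_coverages = cells,
         sd = sqrt(mean((cells - m)^2)),
         mean_coverage = m),
    class = "grid_uniformity"
  )
}

#' Axial coverage profile along the flow axis
#'
#' The ROI is split into `n_bins` contiguous equal-width column bands along
#' the flow axis (inlet at column 0; excess columns trimmed on the outlet
#' side) and bead coverage is computed per band. Plotted against distance
#' from the inlet this profile exposes the saddle-shaped deposition pattern
#' left by the two lobes of the magnet field.
#'
#' @param mask a [binary_mask].
#' @param n_bins number of bands, at least 2 and at most the ROI width.
#'   Default 40.
#' @param pixel_pitch physical length of one pixel along the flow axis; bin
#'   centers are multiplied by it. Default 1 (pixel units).
#' @return An `axial_profile` object with `n_bins`, `bin_centers` (distances
#'   from the ROI inlet edge) and `coverages` (percent per band).
#' @export
axial_profile <- function(mask, n_bins = 40, pixel_pitch = 1) {
  if (!inherits(mask, "binary_mask")) {
    stop("axial_profile: input must be a binary_mask", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1) {
    stop("axial_profile: n_bins must be a positive integer", call. = FALSE)
  }
  px <- roi_pixels(mask)
  w <- ncol(px)
  if (n_bins > w) {
    stop(sprintf("axial_profile: n_bins (%d) exceeds ROI width (%d)",
                 n_bins, w), call. = FALSE)
  }
  bw <- w %/% n_bins
  covs <- numeric(n_bins)
  centers <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    band <- px[, ((b - 1) * bw + 1):(b * bw), drop = FALSE]
    covs[b] <- 100 * sum(band) / length(band)
    centers[b] <- ((b - 1) * bw + bw / 2) * pixel_pitch
  }
  structure(
    list(n_bins = n_bins, bin_centers = centers, coverages = covs),
    class = "axial_profile"
  )
}

#' Mean coverage deviation between two axial profiles
#'
#' Quantifies how much a disturbance (typically the passage of an air gap
#' between liquids) redistributed or removed beads: the mean over bins of the
#' absolute coverage difference between the pre- and post-disturbance
#' profiles. The signed mean difference (post minus pre) is attached as the
#' `"signed_mean"` attribute, since air gaps can both strip beads (negative)
#' and redistribute them.
#'
#' @param pre,post `axial_profile` objects with identical binning.
#' @return Mean absolute per-bin coverage difference, in percent coverage
#'   units, with attribute `signed_mean`.
#' @export
profile_deviation <- function(pre, post) {
  if (!inherits(pre, "axial_profile") || !inherits(post, "axial_profile")) {
    stop("profile_deviation: inputs must be axial_profile objects",
         call. = FALSE)
  }
  if (pre$n_bins != post$n_bins ||
      !isTRUE(all.equal(pre$bin_centers, post$bin_centers))) {
    stop("profile_deviation: profiles have incompatible binning",
         call. = FALSE)
  }
  d <- post$coverages - pre$coverages
  structure(mean(abs(d)), signed_mean = mean(d))
}
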