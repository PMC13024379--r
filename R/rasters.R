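#' Raster containers for the bead-imaging pipeline
#'
#' Images move through the pipeline as three successive plane types:
#' an 8-bit RGB micrograph (`rgb_raster`), an 8-bit grayscale plane
#' (`gray_raster`), and a logical bead/background mask (`binary_mask`)
#' restricted to a rectangular region of interest.
#'
#' Coordinate convention, used everywhere in the package: pixel indices are
#' 0-based, rectangles are half-open `(row0, col0, height, width)`, storage is
#' row-major in the sense that `pixels[r + 1, c + 1]` addresses row `r`,
#' column `c`. The flow axis is the image column axis, with the channel inlet
#' at column 0.
#'
#' @param pixels for `rgb_raster` an `h x w x 3` integer array with values in
#'   0-255; for `gray_raster` an `h x w` integer matrix in 0-255; for
#'   `binary_mask` an `h x w` logical matrix (`TRUE` = bead).
#' @param provenance for `gray_raster`, `"composite"` (straight from channel
#'   combination) or `"enhanced"` (after contrast stretching).
#' @param roi rectangle `c(row0, col0, height, width)` in 0-based half-open
#'   pixel coordinates; for `binary_mask` it records the region the mask was
#'   computed over and defaults to the full plane.
#'
#' @return An object of class `rgb_raster`, `gray_raster` or `binary_mask`.
#' @examples
#' px <- array(120L, dim = c(4, 6, 3))
#' img <- rgb_raster(px)
#' dim(img$pixels)
#' @name rasters
NULL

#' @rdname rasters
#' @export
rgb_raster <- function(pixels) {
  pixels <- check_plane(pixels, n_channels = 3)
  if (nrow(pixels) < 3 || ncol(pixels) < 3) {
    stop("rgb_raster: image must be at least 3x3 pixels", call. = FALSE)
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels)),
    class = "rgb_raster"
  )
}

#' @rdname rasters
#' @export
gray_raster <- function(pixels, provenance = c("composite", "enhanced")) {
  provenance <- match.arg(provenance)
  pixels <- check_plane(pixels, n_channels = 1)
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         provenance = provenance),
    class = "gray_raster"
  )
}

#' @rdname rasters
#' @export
binary_mask <- function(pixels, roi = NULL) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("binary_mask: pixels must be a logical matrix", call. = FALSE)
  }
  if (anyNA(pixels)) stop("binary_mask: NA pixels not allowed", call. = FALSE)
  if (is.null(roi)) roi <- c(0L, 0L, nrow(pixels), ncol(pixels))
  roi <- check_roi(roi, nrow(pixels), ncol(pixels))
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         roi = roi),
    class = "binary_mask"
  )
}

# shared plane validation: integer storage, 0-255 range, non-empty
check_plane <- function(pixels, n_channels) {
  if (n_channels == 3) {
    ok <- is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3
    if (!ok) stop("expected an h x w x 3 array", call. = FALSE)
  } else {
    if (!is.matrix(pixels)) stop("expected an h x w matrix", call. = FALSE)
  }
  if (length(pixels) == 0 || dim(pixels)[1] == 0 || dim(pixels)[2] == 0) {
    stop("empty raster", call. = FALSE)
  }
  if (anyNA(pixels)) stop("raster contains NA values", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  pixels
}

check_roi <- function(roi, height, width) {
  if (length(roi) != 4 || anyNA(roi)) {
    stop("roi must be c(row0, col0, height, width)", call. = FALSE)
  }
  roi <- as.integer(roi)
  if (roi[3] <= 0 || roi[4] <= 0) {
    stop("roi height and width must be positive", call. = FALSE)
  }
  if (roi[1] < 0 || roi[2] < 0 ||
      roi[1] + roi[3] > height || roi[2] + roi[4] > width) {
    stop(sprintf(
      "roi [%d,%d,%d,%d] outside raster bounds %dx%d",
      roi[1], roi[2], roi[3], roi[4], height, width
    ), call. = FALSE)
  }
  roi
}

# extract the ROI submatrix (1-based internally)
roi_pixels <- function(mask) {
  r <- mask$roi
  mask$pixels[(r[1] + 1):(r[1] + r[3]), (r[2] + 1):(r[2] + r[4]), drop = FALSE]
}

#' @export
print.rgb_raster <- function(x, ...) {
  cat(sprintf("<rgb_raster %d x %d>\n", x$height, x$width))
  invisible(x)
}

#' @export
print.gray_raster <- function(x, ...) {
  cat(sprintf("<gray_raster %d x %d, %s>\n", x$height, x$width, x$provenance))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  r <- x$roi
  cat(sprintf("<binary_mask %d x %d, roi [%d,%d,%d,%d], %d bead px>\n",
              x$height, x$width, r[1], r[2], r[3], r[4], sum(roi_pixels(x))))
  invisible(x)
}
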