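#' Parameters for the synthetic bead-field generator
#'
#' Describes the probabilistic density map the generator renders: a two-lobe
#' magnet field leaves two bead stripes across the channel, producing a
#' saddle-shaped axial coverage profile whose first (inlet-side) peak is
#' taller than the second because the inlet-side lobe captures beads first.
#' The map is a background density plus the product of an axial saddle (two
#' Gaussian stripes along the flow axis) and two lateral Gaussian bands
#' across the channel, rescaled so the expected coverage hits
#' `mean_coverage`. This is a statistical emulation of the deposition
#' pattern, not a magnetostatic simulation.
#'
#' @param height,width ROI dimensions in pixels. Defaults 128 x 512 (flow
#'   axis = columns).
#' @param mean_coverage target expected coverage, percent. Default 30.
#' @param stripe_centers axial positions of the two stripes as fractions of
#'   the channel length, first < second. Default `c(0.22, 0.78)`.
#' @param stripe_widths Gaussian SDs of the stripes, channel-length
#'   fractions. Default `c(0.10, 0.12)`.
#' @param peak_ratio first-peak to second-peak density ratio, > 1.
#'   Default 1.5.
#' @param lateral_centers centers of the two lateral bands, channel-height
#'   fractions. Default `c(0.30, 0.70)`.
#' @param lateral_width Gaussian SD of the lateral bands, channel-height
#'   fraction. Default 0.20.
#' @param background bead probability far from the stripes, in `[0, 1)`.
#'   Default 0.04.
#' @param seed integer RNG seed. Default 20260313.
#' @return A `bead_field_params` object.
#' @export
bead_field_params <- function(height = 128, width = 512, mean_coverage = 30,
                              stripe_centers = c(0.22, 0.78),
                              stripe_widths = c(0.10, 0.12),
                              peak_ratio = 1.5,
                              lateral_centers = c(0.30, 0.70),
                              lateral_width = 0.20,
                              background = 0.04,
                              seed = 20260313) {
  stopifnot(height >= 3, width >= 3,
            mean_coverage > 0, mean_coverage < 100,
            length(stripe_centers) == 2,
            all(stripe_centers > 0), all(stripe_centers < 1),
            stripe_centers[1] < stripe_centers[2],
            all(stripe_widths > 0), peak_ratio > 1,
            background >= 0, background < 1)
  structure(as.list(environment()), class = "bead_field_params")
}

# density map on [0,1]x[0,1] fractions; rows = lateral, cols = axial
bead_density_map <- function(params) {
  p <- params
  x <- (seq_len(p$width) - 0.5) / p$width    # axial fraction per column
  y <- (seq_len(p$height) - 0.5) / p$height  # lateral fraction per row
  axial <- p$peak_ratio * exp(-((x - p$stripe_centers[1]) / p$stripe_widths[1])^2 / 2) +
    exp(-((x - p$stripe_centers[2]) / p$stripe_widths[2])^2 / 2)
  lateral <- exp(-((y - p$lateral_centers[1]) / p$lateral_width)^2 / 2) +
    exp(-((y - p$lateral_centers[2]) / p$lateral_width)^2 / 2)
  stripe <- outer(lateral, axial)
  target <- p$mean_coverage / 100
  if (target < p$background) {
    stop("bead_density_map: mean_coverage below the background density",
         call. = FALSE)
  }
  scale <- (target - p$background) / mean(stripe)
  dens <- p$background + scale * stripe
  if (max(dens) > 1) {
    stop(sprintf(
      "bead_density_map: mean_coverage %.1f%% unattainable (peak probability %.3f > 1)",
      p$mean_coverage, max(dens)), call. = FALSE)
  }
  dens
}

#' Generate a synthetic bead-distribution micrograph with ground truth
#'
#' Draws each pixel independently as bead with the probability given by the
#' density map of `params`, then renders the field as an 8-bit RGB
#' micrograph: bead pixels yellow-green (high red and green, low blue),
#' electrode pixels dark gray, plus per-channel Gaussian sensor noise
#' (SD 5 gray levels). The ground-truth mask and density map are returned
#' alongside the rendering so every estimator in the imaging pipeline can be
#' scored against truth.
#'
#' @param params a [bead_field_params].
#' @return A list with `image` ([rgb_raster]), `mask` (ground-truth
#'   [binary_mask]), `density` (matrix of bead probabilities) and `params`.
#' @export
generate_bead_image <- function(params = bead_field_params()) {
  stopifnot(inherits(params, "bead_field_params"))
  dens <- bead_density_map(params)
  set.seed(params$seed)
  h <- params$height; w <- params$width
  bead <- matrix(stats::runif(h * w) < dens, h, w)
  n_bead <- sum(bead)

  r <- g <- b <- matrix(0, h, w)
  r[bead] <- stats::runif(n_bead, 180, 220)
  g[bead] <- stats::runif(n_bead, 190, 230)
  b[bead] <- stats::runif(n_bead, 40, 80)
  gray_bg <- stats::runif(h * w - n_bead, 40, 70)
  r[!bead] <- gray_bg; g[!bead] <- gray_bg; b[!bead] <- gray_bg

  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  px <- px + stats::rnorm(length(px), sd = 5)
  px <- round(pmin(pmax(px, 0), 255))
  storage.mode(px) <- "integer"

  list(image = rgb_raster(px), mask = binary_mask(bead),
       density = dens, params = params)
}

#' Parameters of the crescent-shaped air-gap removal defect
#'
#' An air gap aspirated between liquids can strip already-deposited beads as
#' it passes; the imprint is a crescent-shaped depleted region, centred by
#' default on the second (downstream) bead stripe, with the crescent opening
#' facing the outlet. The region is a disc minus a second disc of equal
#' radius offset toward the outlet.
#'
#' @param center axial position of the crescent centre as a fraction of the
#'   ROI width. Default 0.78 (the second stripe).
#' @param radius disc radius as a fraction of the ROI height. Default 0.6.
#' @param offset displacement of the subtracted disc toward the outlet, as a
#'   fraction of `radius`. Default 0.5.
#' @param severity probability that a bead pixel inside the crescent is
#'   removed, in `[0, 1]`. Default 0.8.
#' @param seed integer RNG seed. Default 20260313.
#' @return An `air_gap_defect_params` object.
#' @export
air_gap_defect_params <- function(center = 0.78, radius = 0.6, offset = 0.5,
                                  severity = 0.8, seed = 20260313) {
  stopifnot(center > 0, center < 1, radius > 0, offset > 0,
            severity >= 0, severity <= 1)
  structure(as.list(environment()), class = "air_gap_defect_params")
}

#' Crescent footprint of an air-gap defect
#'
#' Logical matrix (over the full mask plane) marking the pixels the defect
#' of `params` can touch; exposed so that locality analyses can identify the
#' axial bins that overlap the crescent.
#'
#' @param mask a [binary_mask] (supplies the plane dimensions).
#' @param params an [air_gap_defect_params].
#' @return Logical matrix of the same dimensions as `mask$pixels`.
#' @export
air_gap_crescent <- function(mask, params) {
  stopifnot(inherits(mask, "binary_mask"),
            inherits(params, "air_gap_defect_params"))
  h <- mask$height; w <- mask$width
  rad <- params$radius * h
  c_row <- (h + 1) / 2
  c_col <- params$center * w
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  d_main <- (rows - c_row)^2 + (cols - c_col)^2
  d_cut <- (rows - c_row)^2 + (cols - (c_col + params$offset * rad))^2
  cres <- d_main <= rad^2 & d_cut > rad^2
  if (!any(cres)) {
    stop("air_gap_crescent: crescent does not intersect the mask plane",
         call. = FALSE)
  }
  cres
}

#' Apply a crescent-shaped air-gap bead-removal defect
#'
#' Bead pixels inside the crescent footprint are flipped to background
#' independently with probability `severity`; pixels outside are untouched,
#' so coverage is non-increasing and any profile change is confined to bins
#' overlapping the crescent.
#'
#' @param mask a [binary_mask] (typically a ground-truth bead field).
#' @param params an [air_gap_defect_params].
#' @return A [binary_mask] with the same ROI.
#' @export
apply_air_gap_defect <- function(mask, params = air_gap_defect_params()) {
  cres <- air_gap_crescent(mask, params)
  px <- mask$pixels
  set.seed(params$seed)
  hit <- px & cres
  if (params$severity > 0 && any(hit)) {
    remove <- stats::runif(sum(hit)) < params$severity
    px[hit][remove] <- FALSE
  }
  binary_mask(px, roi = mask$roi)
}

#' Parameters for the synthetic voltage-trace generator
#'
#' Emulates the raw log-amplifier output during an ECL excitation: a noisy
#' baseline current, a luminescence pulse of known total charge `q_star`
#' starting at `onset`, and the forward logarithmic transform to voltage.
#' The pulse is gamma-shaped (sharp rise, exponential-like decay); with the
#' default shape 2 / rate 30 per second, 99.99% of the pulse charge falls in
#' the 0.4 s after onset, and the exact in-window fraction is reported with
#' the ground truth.
#'
#' @param sampling_rate samples per second. Default 1000.
#' @param duration trace length in seconds; must be at least `onset + 0.4`.
#'   Default 3.
#' @param baseline baseline current (units of the model's `i_ref`), > 0.
#'   Default 1.
#' @param onset pulse start time in seconds; must be at least 0.4 so a full
#'   background window precedes it. Default 1.
#' @param q_star true injected pulse charge (current units times seconds),
#'   >= 0. Default 50.
#' @param pulse_shape,pulse_rate gamma shape (unitless) and rate (1/s) of
#'   the pulse profile. Defaults 2 and 30.
#' @param noise_sd Gaussian current-noise SD. Default 0.02.
#' @param model the [log_amp_model] applied to convert current to voltage.
#' @param seed integer RNG seed. Default 20260313.
#' @return A `trace_gen_params` object.
#' @export
trace_gen_params <- function(sampling_rate = 1000, duration = 3,
                             baseline = 1, onset = 1, q_star = 50,
                             pulse_shape = 2, pulse_rate = 30,
                             noise_sd = 0.02, model = log_amp_model(),
                             seed = 20260313) {
  stopifnot(sampling_rate > 0, baseline > 0, q_star >= 0,
            onset >= 0.4, duration >= onset + 0.4,
            pulse_shape > 0, pulse_rate > 0, noise_sd >= 0,
            inherits(model, "log_amp_model"))
  structure(as.list(environment()), class = "trace_gen_params")
}

#' Generate a synthetic voltage-time trace with known injected charge
#'
#' Builds the current trace `baseline + pulse + noise`, where the pulse
#' integrates to `q_star` over all time, then applies the forward
#' log-amplifier transform. The returned ground truth includes the exact
#' fraction of `q_star` that falls inside the 0.4-s target window (closed
#' form of the gamma profile), which is what an ideal processor recovers.
#'
#' @param params a [trace_gen_params].
#' @param window_len target-window length used to report the in-window
#'   charge fraction. Default 0.4.
#' @return A list with `trace` ([voltage_trace]), `q_star`, `onset`,
#'   `target_fraction` (share of `q_star` inside
#'   `[onset, onset + window_len)`), `q_in_window` and `params`.
#' @export
generate_vt_trace <- function(params = trace_gen_params(), window_len = 0.4) {
  stopifnot(inherits(params, "trace_gen_params"))
  p <- params
  times <- seq(0, p$duration, by = 1 / p$sampling_rate)
  pulse <- p$q_star * stats::dgamma(pmax(times - p$onset, 0),
                                    shape = p$pulse_shape, rate = p$pulse_rate)
  set.seed(p$seed)
  current <- p$baseline + pulse +
    if (p$noise_sd > 0) stats::rnorm(length(times), sd = p$noise_sd) else 0
  if (any(current <= 0)) {
    stop("generate_vt_trace: noise drove the current non-positive; ",
         "reduce noise_sd or raise baseline", call. = FALSE)
  }
  trace <- forward_log_amp(list(times = times, currents = current), p$model)
  frac <- stats::pgamma(window_len, shape = p$pulse_shape, rate = p$pulse_rate)
  list(trace = trace, q_star = p$q_star, onset = p$onset,
       target_fraction = frac, q_in_window = frac * p$q_star, params = p)
}

#' Generate a noiseless-or-noisy calibration dataset
#'
#' Evaluates a linear concentration-response model at the supplied
#' calibrator concentrations, optionally adding Gaussian intensity noise:
#' `intensity = slope * concentration + intercept + N(0, noise_sd)`.
#'
#' @param concentrations calibrator concentrations (same units as the
#'   model), non-empty.
#' @param slope,intercept generating line.
#' @param noise_sd Gaussian intensity-noise SD. Default 0 (noiseless).
#' @param seed integer RNG seed (used only when `noise_sd > 0`).
#'   Default 20260313.
#' @return Data frame with columns `concentration`, `intensity`.
#' @export
generate_calibration_dataset <- function(concentrations, slope, intercept,
                                         noise_sd = 0, seed = 20260313) {
  stopifnot(length(concentrations) > 0, is.finite(slope), is.finite(intercept),
            noise_sd >= 0)
  intensity <- slope * concentrations + intercept
  if (noise_sd > 0) {
    set.seed(seed)
    intensity <- intensity + stats::rnorm(length(concentrations), sd = noise_sd)
  }
  data.frame(concentration = concentrations, intensity = intensity)
}

#' Illustrative crowding-limited luminescence yield of a bead field
#'
#' A deliberately simple coupling between bead distribution and integrated
#' luminescence: each bead pixel contributes `1 / (1 + beta * d)` where `d`
#' is the local bead density (mean of the mask over a square neighborhood),
#' so crowded regions yield less light per bead. At equal coverage, a more
#' uniform field therefore produces a larger total signal — a qualitative
#' analogue of the uniformity-signal link, not a calibrated physical model.
#'
#' @param mask a [binary_mask].
#' @param beta crowding strength, >= 0. Default 2.
#' @param radius half-width of the square density neighborhood in pixels.
#'   Default 4.
#' @return Total yield (arbitrary units).
#' @export
ecl_yield <- function(mask, beta = 2, radius = 4) {
  stopifnot(inherits(mask, "binary_mask"), beta >= 0, radius >= 1)
  px <- roi_pixels(mask)
  dens <- box_mean(px * 1, radius)
  sum(1 / (1 + beta * dens[px]))
}

# mean over a (2r+1)^2 neighborhood via integral image, edge-truncated
box_mean <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  s <- matrix(0, h + 1, w + 1)
  s[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    r0 <- max(i - r, 1); r1 <- min(i + r, h)
    for (j in seq_len(w)) {
      c0 <- max(j - r, 1); c1 <- min(j + r, w)
      tot <- s[r1 + 1, c1 + 1] - s[r0, c1 + 1] - s[r1 + 1, c0] + s[r0, c0]
      out[i, j] <- tot / ((r1 - r0 + 1) * (c1 - c0 + 1))
    }
  }
  out
}
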