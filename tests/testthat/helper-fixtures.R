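# In-code fixtures and independent oracles shared across the suite.

# uniform RGB raster of one color
uniform_rgb <- function(h, w, rgb) {
  px <- array(0L, dim = c(h, w, 3))
  px[, , 1] <- as.integer(rgb[1])
  px[, , 2] <- as.integer(rgb[2])
  px[, , 3] <- as.integer(rgb[3])
  rgb_raster(px)
}

random_mask <- function(h, w, p = 0.5) {
  binary_mask(matrix(stats::runif(h * w) < p, h, w))
}

# brute-force coverage: explicit double loop over the ROI, no vectorization
coverage_oracle <- function(mask) {
  r <- mask$roi
  n_bead <- 0L
  for (i in (r[1] + 1):(r[1] + r[3])) {
    for (j in (r[2] + 1):(r[2] + r[4])) {
      if (mask$pixels[i, j]) n_bead <- n_bead + 1L
    }
  }
  100 * n_bead / (r[3] * r[4])
}

# direct nine-term population SD of given cell coverages
grid_sd_oracle <- function(cells) {
  m <- sum(cells) / 9
  sqrt(sum((cells - m)^2) / 9)
}

# direct-formula Pearson correlation
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# the ten calibrator concentrations of the TSH linearity series (uIU/mL)
tsh_concentrations <- c(0.016, 0.02, 0.08, 0.2, 0.8, 2, 8, 20, 60, 120)
tsh_slope <- 38383.2
tsh_intercept <- -397430

# constant-voltage trace helper
flat_trace <- function(v, duration = 2, dt = 0.001) {
  times <- seq(0, duration, by = dt)
  voltage_trace(times, rep(v, length(times)))
}

# sample n labeled grayscale values of each class from a ground-truth mask
labeled_samples <- function(gray, truth_mask, n = 200) {
  bead_idx <- which(truth_mask$pixels)
  el_idx <- which(!truth_mask$pixels)
  list(bead = gray$pixels[sample(bead_idx, n)],
       electrode = gray$pixels[sample(el_idx, n)])
}

# full imaging pipeline from rendered image + truth-derived calibration
pipeline_coverage <- function(sim, n_labels = 200) {
  gray <- enhance_contrast(rg_composite(sim$image))
  s <- labeled_samples(gray, sim$mask, n_labels)
  model <- calibrate_threshold(s$bead, s$electrode)
  coverage(binarize(gray, model))
}
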