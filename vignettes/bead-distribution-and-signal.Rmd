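---
title: "Quantifying magnetic-bead distribution and ECL detector signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying magnetic-bead distribution and ECL detector signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadmetrics)
```

## The measurement problem

In a bead-based electrochemiluminescence immunoassay (ECLIA), streptavidin
magnetic beads carrying sandwich immunocomplexes are pulled onto a platinum
working electrode by a permanent magnet, and an applied potential drives
the Ru(bpy)₃²⁺/TPrA reaction whose photons a PMT converts to current.
Because the reaction is surface-confined — the emitting species must sit
within a few micrometers of the electrode — the *spatial arrangement* of
the beads, not only their amount, determines the light yield. Crowded,
multilayered deposits shade and starve each other; an even monolayer emits
more per bead. `beadmetrics` provides the quantitative layer for tuning
fluidic parameters (flow velocity, acceleration time, air-gap volume)
against that arrangement: an imaging chain that measures *how much* and
*how evenly* beads cover the electrode, and a signal chain that turns the
detector's raw voltage trace into a background-corrected charge.

## The imaging chain

The micrograph model is simple and deliberate: beads appear yellow–green
(strong red and green, weak blue), the exposed electrode dark gray. The
chain is

1. **Channel compositing** (`rg_composite`). The blue channel reduces
   bead/electrode contrast, so it is discarded and the composite plane is
   the per-pixel mean of red and green. How the two channels should be
   combined is genuinely open (sum, mean, max are all defensible); the
   unweighted mean is the simplest symmetric choice, keeps the 0–255
   range, and the choice is recorded in every report's parameter block.
   Rounding is half-up (`floor(x + 0.5)`), not banker's rounding, so `.5`
   cases are deterministic across platforms.
2. **Contrast stretch** (`enhance_contrast`). A linear percentile stretch
   maps the 1st percentile to 0 and the 99th to 255, clipping outside.
   Percentile anchors rather than min/max make the map robust to isolated
   hot or dead pixels; a constant image is returned unchanged rather than
   divided by zero. This is the only illumination handling the package
   does — no flat-field correction.
3. **Threshold calibration** (`calibrate_threshold`). Grayscale values
   sampled inside the channel are labeled bead or electrode; the
   binarization threshold is the midpoint of the two class means. With
   non-overlapping class ranges (the regime the instrument's optics are
   set up to deliver, and which the synthetic renderer reproduces) the
   midpoint classifies every pixel correctly; the estimator is also
   monotone and indifferent to class imbalance, unlike a pooled-variance
   cut. An explicit threshold can be supplied instead
   (`threshold_model`), e.g. from a run configuration.
4. **Binarization and statistics**. A pixel is bead if it lies on the bead
   side of the threshold (`>=` when the bead class is brighter; the
   boundary value belongs to the bead class by convention). Coverage is
   the bead-pixel fraction of the region of interest, in percent.

Rectangles are 0-based and half-open, `(row0, col0, height, width)`; the
flow axis is the column axis with the inlet at column 0. These conventions
are stated once here and used everywhere.

**Uniformity.** The ROI is partitioned into nine equal rectangles in a
3 × 3 grid and the *population* SD (divisor 9) of the nine cell coverages
is the uniformity metric. With a fixed divisor the metric is a pure
function of the nine numbers and scale-stable across runs; whether a
sample divisor was intended is unknowable from a printed SD, and n = 9 is
a census of the grid, not a sample from it. When the ROI dimensions are
not divisible by 3, bottom and right (outlet-side) pixels are trimmed
rather than letting cells differ by a row or column — the cells stay
*exactly* equal, which is what makes the mean-of-cells identity
(`mean(cell_coverages) == coverage` on divisible ROIs) exact.

**Axial profile.** The ROI is cut into `n_bins` equal-width column bands
(default 40; excess columns again trimmed on the outlet side) and coverage
is computed per band against its center distance from the inlet. Forty
bins resolves the two deposition stripes at the default geometry while
keeping ≥ 1000 pixels per band on a 512-wide image, so per-band binomial
noise stays below ~1.5 % absolute. `profile_deviation` compares two
profiles with identical binning by the mean *absolute* per-bin difference:
an air gap can both strip beads (one sign) and redistribute them (both
signs), and a signed mean would let the two cancel. The signed mean is
still reported as an attribute, since its sign separates net removal from
pure redistribution.

## The signal chain

The PMT current passes through a logarithmic amplifier. The instrument's
transfer constants are not public, so the package uses an explicit
decade-log model with all three parameters in the open:

$$V = g \log_{10}(I / I_\mathrm{ref}) + V_\mathrm{off}, \qquad
  I = I_\mathrm{ref} \, 10^{(V - V_\mathrm{off})/g}$$

with defaults $g = 1$ V/decade, $V_\mathrm{off} = 0$, $I_\mathrm{ref} = 1$
(so reconstructed currents are in units of $I_\mathrm{ref}$). Any real
amplifier's constants can be dropped in; the inversion is exact for
whatever constants are supplied, which is what the round-trip tests check
(forward then inverse agrees to better than 1e−9 relative).

**Onset.** The luminescence pulse begins when the potential sweep reaches
the reaction; locating that instant from the trace alone is plumbing the
package must define. `detect_onset` computes baseline mean μ and SD σ over
the first 0.4 s and takes the first sample with $V > \mu + k\sigma$
(default $k = 5$); because a finite rise can cross a 5σ bar a few samples
late, the estimate then walks back over immediately preceding samples
still above $\mu + \sigma$ and anchors on the first sample of that rising
run. An explicit onset override bypasses detection for scripted
experiments where the excitation time is known.

**Charge.** Two adjacent half-open 0.4-s windows are formed — background
$[t_0 - 0.4, t_0)$ and target $[t_0, t_0 + 0.4)$ — and the reconstructed
current is integrated over each by the trapezoid rule, with the window
endpoints obtained by linear interpolation when they fall between samples.
The 0.4-s length is the window over which the charge integral stays linear
in the luminescence on the instrument this models; it is a parameter
(`window_len`), not a constant. The luminescence charge is

$$Q_\mathrm{photon} = S_\mathrm{target} - S_\mathrm{noise},$$

which cancels any stationary background exactly (tested to 1e−12 under
constant current offsets). Negative values — possible at zero true signal
under noise — are returned as-is with a quality flag, never clamped, so
replicate averages stay unbiased.

One ambiguity deserves a paragraph: the quantity is a *charge*, i.e. the
integral of the reconstructed current, yet integrating the raw voltage
over the same windows is also a defensible (and on some instruments,
implemented) definition of "intensity". The package integrates the
current by default — that is the reading consistent with calling the
result $Q$ — and offers `integrate = "voltage"` in `process_trace` for
side-by-side comparison. The two differ by the log-amp nonlinearity and
are not proportional.

**Trapezoid exactness.** The trapezoid rule is exact for constant and
linear integrands, which the test suite uses as closed-form oracles; for
the gamma-shaped synthetic pulse at 1 kHz sampling, discretization plus
one-sample onset quantization keeps the recovered charge within 2 % of
the injected in-window charge, and in practice within ~0.1 %.

## Assay analytics

* `fit_calibration` — ordinary least squares of intensity on
  concentration, on raw axes, matching the single linear fit instruments
  apply across roughly four decades of concentration. A weighted or
  log-log fit would change the printed slope's meaning; a log-log mode
  exists for diagnostics but is off by default. R² is computed as
  $1 - SS_\mathrm{res}/SS_\mathrm{tot}$ from the same fit.
* `coefficient_of_variation` — sample SD (n − 1), the clinical-lab
  convention for replicate sets of ~10.
* `compare_methods` — OLS of test on reference with R² equal to the
  squared Pearson correlation. Bland–Altman bias analysis is deliberately
  out of scope.
* `select_optimal_condition` — the verbal rule "coverage high, SD
  minimized" made operational: among sweep points with coverage at least
  `alpha` times the maximum (default `alpha = 0.9`), take the minimum-SD
  point, tie-breaking toward lower flow velocity (gentler handling at
  equal merit). On a sweep where the slowest velocity has the highest
  coverage but much the worst SD, any `alpha` ≲ 0.95 selects the
  low-SD/near-maximal-coverage point; `alpha = 1` degenerates to the pure
  coverage maximizer. The default 0.9 accepts up to a 10 % coverage
  concession for uniformity, which is the trade the sweep data motivate.
* Saturation handling: PMT gain compresses at high photon flux, so
  calibration points above the linear range are handled by per-point
  exclusion before fitting, not by a saturation model.

## What the synthetic generators emulate — and what they do not

`generate_bead_image` renders a *probabilistic density map*, not bead
physics: bead probability = background + scale × (axial saddle × two
lateral bands), where the axial saddle is two Gaussians at fractions 0.22
and 0.78 of the channel length (SDs 0.10 and 0.12) with the first peak
`peak_ratio` (default 1.5) times the second — the inlet-side magnet lobe
captures beads first, so its stripe is denser — and the lateral bands sit
at height fractions 0.30 and 0.70 (SD 0.20). The scale is chosen in closed
form so the *expected* coverage equals `mean_coverage` (default 30 %);
targets that would push any pixel's probability above 1 raise an error
rather than clip, because clipping would silently bias the realized
coverage below target. Pixels are drawn independently, so on a 512 × 128
ROI the realized truth coverage has binomial SD ≈ 0.18 % — this is what
makes ±1 % truth-vs-target assertions meaningful. Rendering uses bead RGB
in (180–220, 190–230, 40–80), electrode gray in (40–70), plus per-channel
Gaussian sensor noise (SD 5): separable classes by construction, so the
default calibration achieves exact pixel classification, while overlap
experiments remain possible by narrowing the gap in configuration.

Not emulated: magnetostatics and fluid dynamics (no field model, no shear
model), bead size distributions and instance boundaries (coverage is pure
area fraction), illumination gradients, and spatially correlated bead
clumping. Passing the end-to-end tests therefore shows the *estimators*
are correct on fields with the right first-order structure; it does not
validate the optics of any real microscope.

`apply_air_gap_defect` imprints the passage of a badly sized air gap:
inside a crescent (a disc of radius 0.6 × ROI height minus an equal disc
offset toward the outlet, centered by default on the second stripe — the
deposit the gap hits after traversing the channel), bead pixels flip to
background with probability `severity`. Pixels outside are untouched, so
coverage is non-increasing in severity and profile deviation restricted to
bins outside the crescent is *exactly* zero — the locality property the
tests assert.

`generate_vt_trace` builds current = baseline + pulse + Gaussian noise and
applies the forward log-amp model. The pulse is gamma-shaped (shape 2,
rate 30 s⁻¹): zero at onset, fast rise, exponential-like decay, with total
area `q_star` and a closed-form in-window fraction
(`pgamma(0.4, 2, 30)` ≈ 0.99992) reported in the ground truth — the
processor is scored against the in-window charge, not total `q_star`, so
the generator never hides a truncation error. Defaults: 1 kHz sampling,
3 s duration, onset at 1 s, baseline 1, noise SD 0.02 (2 % of baseline).
The constraint `onset ≥ 0.4 s` guarantees a full background window exists.

`ecl_yield` is an *illustrative* crowding model — each bead pixel
contributes $1/(1 + \beta d)$ with $d$ the local bead density — included
only to demonstrate qualitatively that, at equal coverage, the
lower-SD field integrates more light. It is clearly not the instrument's
bead-to-photon coupling, and no quantitative effect size is claimed from
it.

All generators take explicit integer seeds (default 20260313) and are
bitwise reproducible at fixed seed.

## Problem sizes and numerical tolerances

The test suite and the reproduction script use: 200 random masks (≤ 64 ×
64) for the pixel-count oracle; 100 random model/trace pairs for the
log-amp round trip (1e−9 relative); 20 seeded 96 × 320 bead fields for
end-to-end coverage recovery (2 % absolute) and 20 noiseless traces for
charge recovery (2 % relative); 100 seeds for the zero-signal
unbiasedness check (|mean| < 3 SE); and 100 replicate pairs at 96 × 240
for the flat-vs-peaked uniformity ordering. The uniformity comparison runs
at 20 % mean coverage because a `peak_ratio` of 3 cannot reach 30 %
without the density map saturating (the generator refuses by design);
20 % keeps both fields comfortably inside the valid probability range.
Exact identities (baseline-offset cancellation, integral additivity, CV
scale invariance) are asserted at 1e−12 relative, i.e. accumulated
floating-point slack only.

## Known limitations

* Coverage is resolution-dependent at bead scale: a pixel is either bead
  or not, so partial-pixel occupancy biases coverage slightly upward at
  coarse magnification. The package does not model sub-pixel area.
* The midpoint threshold assumes unimodal, separated class distributions;
  heavily overlapping classes need either more labeled samples or an
  explicit threshold. No automatic bimodal fallback is enabled by default.
* Onset detection assumes a quiet pre-reaction baseline at least 0.4 s
  long; drifting baselines should use the onset override.
* The 3 × 3 grid SD conflates lateral and axial non-uniformity; the axial
  profile is the finer instrument for axial structure.
* All effect sizes measured on synthetic data (e.g. the yield gain of a
  flatter field) are properties of the generator's assumptions, and no
  correspondence with any instrument's measured percentages is asserted.
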