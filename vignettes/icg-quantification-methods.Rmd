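---
title: "Quantifying ICG fluorescence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ICG fluorescence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgquant)
```

This vignette is the package's own account of what it computes, the
assumptions behind each step, and the choices made where the underlying
method left the design open.

## The measurement model

A fluorescence-mode laparoscopic still renders the ICG signal as green on
screen. The image is an 8-bit RGB raster: three integer matrices R, G, B on
the 0–255 scale. We take the green channel inside a region of interest as a
proxy for the local ICG fluorescence intensity, under two assumptions:

* the rendering pipeline maps fluorescence monotonically to the green
  channel (true of devices that display the infrared signal as a green
  overlay; not true of grey-scale renderers, which are out of scope);
* acquisition conditions (dose, time after injection, camera distance,
  light source, intra-abdominal pressure) are held constant across the
  acquisitions being compared, so intensities are comparable. The package
  cannot check this; it is the experimental design's job.

Two artefacts corrupt a naive green-channel average: **specular
reflections** of the light source on wet tissue, rendered white or
near-white, and **visible vessels**, which saturate towards the 255
ceiling and clip. Each gets its own defence.

### Green dominance

A pixel is retained iff `G > R` and `G > B`, with strict inequalities. A
white reflection (R = G = B = 255) fails the test, as does any neutral
grey; retained pixels are exactly those the display renders as
green-dominant, i.e. signal. The rule is deliberately parameter-free: it
needs no threshold tuned to a particular device's white point. Ties are
discarded because a pixel whose green merely equals another channel is not
predominantly green; this is the minimal consistent reading of
"predominant", and it makes the achromatic axis (R = G = B) unreachable by
construction — an invariant the test suite asserts.

Statistics are computed over retained pixels only. An ROI whose retained
fraction falls below `min_retained_fraction` (default 0.5) is flagged as
unrepresentative but still pooled; a fully masked ROI is an error at the
single-ROI level and contributes nothing at the segment level. The 0.5
default is a judgement call: an ROI half-covered by reflection is suspect,
but its surviving pixels are still valid signal, so they are kept and the
flag is surfaced for the analyst.

### ROI statistics and pooling

Per ROI we report n_total, n_retained, mean, sample SD (n−1), median,
quartiles, min, max and a 256-bin histogram. Quartiles use linear
interpolation between order statistics (`quantile()` type 7); the choice is
immaterial for the 100-pixel default ROIs but is fixed and recorded in the
report metadata so exports are reproducible across tools.

The segment-level intensity is the mean of the **union of retained pixels
across all ROIs** — pixel-weighted, not a mean of ROI means. With equal,
fully retained ROIs the two coincide; once masking bites they differ, and
the pixel-weighted form is the one in which every sampled pixel counts
once, whichever square it came from. It also makes the estimator immune to white
contamination in a precise sense: whitening any subset of pixels removes
them from the union but cannot shift the values of the remaining retained
pixels. The suite checks this immunity property directly, and checks the
whole chain against a brute-force per-pixel loop on random 8×8 images
(exact equality, not tolerance).

### Automatic ROI placement

Manual placement of ten 10×10 squares is the reference procedure; the
auto-sampler automates it. It rejection-samples non-overlapping squares
that (a) contain no *retained* pixel with G ≥ `vessel_cutoff` (default
250) and (b) keep at least `min_retained_fraction` retained. The cutoff is
applied to retained pixels only: white reflections also have G = 255, but
they are already excluded by the dominance mask and bounded by the
retained-fraction rule; applying the cutoff to them as well would make
every rectangle inadmissible on images with scattered reflections, while
the cutoff's actual purpose is avoiding green, near-saturated vessel
streaks whose clipped values bias the mean downward-invisibly. Placement is
deterministic given the seed; an inadmissible image yields a sampling
error reporting how many squares were placed, rather than a silent partial
result.

## Perfusion metrics

With segment-level means in hand, define for the ischemic segment:

* **MISPreI** — mean over subjects of the pre-ischemia segment means
  (one value per subject);
* **MISPostI** — pooled mean over *all* post-ischemia determinations,
  across subjects and observation times (a flat average; subjects observed
  at more times carry more weight);
* **AMISD** = MISPreI − MISPostI, in intensity points;
* **RMISD** = (1 − MISPostI/MISPreI) × 100, in percent.

The asymmetric weighting — subject means pre, flat pooling post — is not an
aesthetic choice: it is the only weighting that reproduces both reference
means of the built-in study simultaneously (146.9743 and 99.0839), and
pooling the post phase is defensible because the post-ischemia signal is
stable over time (the by-time ANOVA within the ischemia period is null,
p ≈ 0.385 on the built-in data). Missing observations (animal deaths) are
skipped, never imputed.

Classification uses a closed threshold: ischemic iff RMISD ≥
`threshold_percent`, default 32.6. The default is the relative decrease
measured at surgically complete devascularization of the porcine left
colon; it is an experimental estimate from one model, not a clinical
reference value, which is why it is a parameter and why the built-in
study's own unrounded RMISD (32.5842%) sits just below it — the package
reports that boundary case as not-ischemic rather than rounding first.

## The statistical toolkit

Descriptive CIs are two-sided Student-t intervals,
mean ± t(n−1, 0.975)·sd/√n. Two-group comparisons use the **pooled
(equal-variance) unpaired t-test** with df = n₁+n₂−2; this is the form
whose CI for the difference reproduces the built-in study's printed
comparison table exactly, and the regression suite pins all ten rows of it.
By-time stability is tested with standard unbalanced one-way ANOVA
(F = MSB/MSW). Two scopes are reported: post-times-only (stability within
the ischemia period) and all-times (stability of the whole experiment);
on the built-in data these reproduce the two reference p-values 0.385 and
0.889 respectively — resolving, by recomputation, which groups each ANOVA
must have covered.

Normality screening is one-sample Kolmogorov–Smirnov against a normal with
the sample's own mean and SD. Estimating the parameters from the same data
makes the classical p-value conservative; this is the common
statistics-package default and is kept as the default here for
comparability, with the caveat attached to every result and a
Lilliefors-corrected variant (`lilliefors = TRUE`, via the nortest package)
available when calibrated p-values matter. No multiple-testing correction
is applied anywhere — the comparison table mirrors the reference analysis —
but a note is emitted whenever more than two uncorrected comparisons are
run in one report.

Report rounding: tabular CSVs are written at 4 decimals and headline
values print at 1 decimal, matching the field's reporting convention; JSON
always keeps raw precision.

## The built-in fixture

The package embeds the complete per-animal measurement matrix of a
controlled porcine experiment: both colon segments of each animal measured
before ischemia, then the left-colon vascular arcade divided and both
segments re-measured at 15, 45, 75, 105 and 135 minutes. One animal's
post-ischemia data and two animals' late time points are missing
(cardiorespiratory arrest), leaving 7 pre-phase animals and 31 post-phase
observations per segment. Two transcription quirks are preserved
deliberately:

* the pre phase labels its animals 1,2,3,5,6,7,8 and the post phase
  1,2,4,5,6,7,8; the fixture keeps each phase's own labels and no code
  path joins subjects across phases;
* the source's reported post-period right-colon mean of 140.0 is not
  reproducible from the printed values (the pooled mean is 141.25, the
  mean of per-time means 140.93); the fixture documents rather than
  matches it, and nothing asserts it.

`builtin_study()` recomputes all twelve per-group means on every call and
aborts if they drift from the transcription checksums, so the fixture
cannot silently decay.

## Synthetic generators

`generate_synthetic_image()` emulates exactly the features the filter and
sampler must handle: a uniform green field `base_green` with i.i.d.
Gaussian pixel noise (clipped to [0, 255]) over a dim red/blue background,
pure-white reflection pixels at an exact fraction of positions, and
2-pixel-wide vertical G = 255 vessel streaks, all positions recorded as
ground truth. Defaults (256×256, base 147, noise SD 8, 10% reflections, 2
vessels, background 60) mirror a well-perfused segment at the study's
intensity scale with moderate contamination. What it does **not** emulate:
spatial intensity gradients, JPEG compression artefacts, motion blur,
correlated (textured) noise, and curved vessels. Passing tests therefore
demonstrate correctness of the pixel arithmetic and estimator under the
stated contamination model, not robustness to every optical artefact of
real laparoscopy.

`simulate_study()` draws per-subject, per-segment pre-ischemia levels
Normal(`mu_pre`, `sigma_between`), control-segment post values around the
subject's own pre level with SD `sigma_time`, and ischemic-segment post
values around `pre · (1 − drop_fraction)` — a multiplicative drop, the
form consistent with a scale-relative metric like RMISD (an additive drop
would make RMISD depend on the subject's baseline brightness). Late time
points are lost per subject with probability `dropout_prob`. Defaults
(8 subjects, mu 147, between-subject SD 13, within-subject SD 5, drop
0.326, dropout 0.15) are set once to the study conditions of the porcine
experiment: its observed pre-phase mean and between-animal spread, its
post-phase temporal stability, its headline drop, and its observed loss of
late observations in a quarter of animals. Clipping at [0, 255] is active
in principle but negligible in this regime: the closed-form mean of a
clipped normal differs from the unclipped mean by < 0.01 intensity units
for levels in [30, 225] and SDs ≤ 10, an analytic bound the suite asserts.

All randomness flows from a single integer seed per call through a private
RNG scope that restores the caller's stream, so identical seeds give
byte-identical outputs and sessions are never perturbed.

## Numerical and degenerate-input choices

* 0-based, row-major, half-open ROI coordinates; out-of-bounds rectangles
  are errors naming the offending extent, never clamped.
* Lossless PNG is the fixture and round-trip format; JPEG is accepted for
  input (it is what laparoscopy towers record) but decoding is
  library-dependent at the pixel level, so nothing quantitative is pinned
  to JPEG fixtures.
* Alpha channels are dropped with a warning; greyscale and non-8-bit
  rasters are rejected.
* A zero-pooled-variance t-test with unequal means returns an
  infinite-t flagged result instead of erroring; with equal means it is
  t = 0, p = 1.
* `rmisd()` with a zero pre-ischemia mean is an undefined-ratio error.
* Empty groups, singleton-only ANOVAs, and n < 2 descriptives are typed
  errors (`icgquant_empty_group`, `icgquant_insufficient_data`), so
  callers can distinguish data problems from bugs.

## Problem sizes used in the checks

The test suite works at desk scale, chosen as the smallest sizes at which
each property is informative: exact-oracle image checks on random 8×8
images (the oracle is a per-pixel loop; exactness does not grow with
size), ground-truth recovery on 128×128 images (≥ 10⁴ retained pixels),
KS calibration at n = 5000 over 100 replicates, null and drop-recovery
simulations over 200 and 500 seeds, and a full image-to-assessment
pipeline over 4 subjects × 6 times × 2 segments of 64×64 images.

## Known limitations

* Intensity is a proxy: absolute values depend on dose, timing, distance
  and device; only within-protocol comparisons are meaningful, and inflow
  kinetics (time-to-peak, slope, half-life) are explicitly out of scope.
* The 32.6% threshold is a single-model estimate at complete
  devascularization; sensitivity/specificity for partial ischemia are
  unknown, and the package treats the threshold as a parameter to be
  recalibrated, not a constant.
* The dominance filter assumes a green-overlay rendering; grey-scale
  fluorescence displays need a different front end.
* Classical KS p-values with estimated parameters are conservative; use
  the Lilliefors variant for calibrated screening.
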