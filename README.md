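# icgquant

Objective quantification of indocyanine green (ICG) fluorescence in surgical
RGB images, and the perfusion metrics built on it.

## The problem

In colorectal surgery, ICG fluorescence angiography is used to judge whether
a bowel segment is well enough perfused to hold an anastomosis: the dye is
injected intravenously, excited with near-infrared light, and rendered as a
green overlay by the fluorescence laparoscope. Read by eye, the green signal
is notoriously observer-dependent. `icgquant` replaces the eyeball with
numbers: it decomposes a still image into its RGB channel matrices, discards
every pixel whose predominant colour is not green, and summarises the green
intensity (0–255 scale) over rectangular regions of interest (ROIs) placed
on the tissue of interest.

The core filter is strict **green dominance**: a pixel is retained iff

```
G > R  and  G > B
```

(ties discarded), which removes white specular reflections — white being
R = G = B = 255 — and neutral greys before any statistic is computed.
Segment intensity is the **pixel-weighted pooled mean** over all retained
pixels of all ROIs (never a mean of ROI means). Perfusion change between a
pre-ischemia and a post-ischemia acquisition is expressed as

```
AMISD = MISPreI − MISPostI                      (absolute decrease, points)
RMISD = (1 − MISPostI / MISPreI) × 100         (relative decrease, %)
```

where MISPreI is the subject-mean pre-ischemia saturation and MISPostI the
pooled mean over *all* post-ischemia determinations. A segment is classified
ischemic when RMISD ≥ 32.6% — the relative decrease observed at complete
devascularization in a porcine colon model, configurable and emphatically
not a clinical constant.

The package also ships the study-level statistical toolkit that accompanies
such an experiment (t-based confidence intervals, pooled two-sample t-tests,
unbalanced one-way ANOVA, Kolmogorov–Smirnov normality screening), the
porcine study's complete measurement matrix as a self-verifying built-in
fixture, and synthetic generators — images with a known green level,
reflections and saturated vessel streaks; study matrices with a known
multiplicative perfusion drop — so the whole chain is testable with known
ground truth.

## Worked example

Quantify a synthetic fluorescence image with known ground truth (green level
147, Gaussian noise SD 8, 10% white reflections, 2 saturated vessel
streaks), placing ten 10×10 sampling squares automatically:

```r
library(icgquant)

gen  <- generate_synthetic_image(height = 256, width = 256, base_green = 147,
                                 noise_sd = 8, reflection_fraction = 0.10,
                                 n_vessels = 2, seed = 7)
img  <- gen$image
mask <- green_dominance_mask(img)
rois <- auto_sample_rois(img, mask, n = 10, size = 10, seed = 7)
quantify_segment(img, rois, mask)
#> <segment_summary> 10 ROIs | pooled mean 146.6134 over 908/1000 retained pixels
```

92 of the 1000 sampled pixels were white reflections and were discarded by
the dominance filter; the pooled mean 146.61 recovers the generated level
147 well within the sampling error of 908 pixels, untouched by reflections
or vessels (the auto-sampler refuses rectangles containing retained pixels
with G ≥ 250).

Assess ischemia on the built-in porcine study (7 animals pre-ischemia, 31
post-ischemia observations of the devascularized left colon):

```r
assess_ischemia(builtin_study(), segment = "left")
#> <ischemia_assessment>
#>   MISPreI  146.9743
#>   MISPostI 99.0839
#>   AMISD    47.9 points
#>   RMISD    32.6%
#>   ischemic at >= 32.6%: no
```

The intensity fell by 47.9 points, a 32.6% relative decrease. (The
unrounded RMISD is 32.5842%, which sits a hair *below* the closed ≥ 32.6%
default cutoff — the cutoff itself is this study's rounded estimate, so the
boundary call is shown honestly; `threshold_percent = 32.5` flags it.)

The full study report — descriptive tables, pre-vs-post pooled t-tests with
CIs, by-time ANOVAs, assessment JSON and boxplot figures — is one call
(`cmd_study("builtin", "out/")`), also available from a shell via the thin
CLI in `exec/`:

```sh
Rscript exec/icgquant study --input builtin --out out/
Rscript exec/icgquant quantify --image still.png --out out/ --n-rois 10
Rscript exec/icgquant simulate --what study --out sim.csv --drop-fraction 0.326 --seed 7
```

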