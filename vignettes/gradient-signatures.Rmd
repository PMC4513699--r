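---
title: "Intensity gradient signatures: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity gradient signatures: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epigrad)
```

## The measurement model

Stratified squamous epithelium matures from the basement membrane to the
surface; in H&E-stained sections the eosin-protein complexes of maturing
keratinocytes fluoresce increasingly brightly towards the surface. The
package quantifies this gradient per annotated basal-to-surface line:

* **Profile.** Intensities are sampled by bilinear interpolation at spacing
  `step` (default 1 px) from the basal endpoint; sample `i` sits at
  `start + i * step * u` with `u` the unit direction. A profile needs at
  least 9 samples (3 per segment).
* **Segments.** The ordered samples are cut into lower/middle/upper thirds.
  When `n` is not divisible by 3 the remainder goes one extra sample per
  segment starting basal-first, so lengths differ by at most one. This rule
  is deterministic and conserves every sample; the classical "0-200 /
  201-400 / 401-600" description of a 600-px line leaves boundary
  membership ambiguous, so the package fixes one convention and tests it.
* **Filtering.** Segment `k` is reduced to `m_k`, the mean of values at or
  above the nearest-rank q-th percentile (`k = ceiling(qn/100)`, ties at
  the threshold all retained). The default q = 89 keeps the top decile
  (slightly more on small n, never an empty set). This is the dark-object
  filter: nuclei and glycogen-rich cytoplasm are essentially
  non-fluorescent, and dropping the lower 89% of each segment removes them
  together with cyclic (estrogen-driven) glycogen variation. "89th
  percentile" and "top 10%" disagree by one percent; nearest-rank at q = 89
  was chosen because it is exactly reproducible and keeps at least 11% of
  samples, and q is configurable throughout.
* **Slope.** An OLS line through `(1, m1), (2, m2), (3, m3)`. With segment
  indices as abscissa the slope is exactly `(m3 - m1)/2` (gray value per
  segment step). The abscissa convention is not dictated by the measurement
  itself; segment indices reproduce raw slopes of the expected magnitude
  for 32-bit captures and make the algebra transparent. A
  `pixel_midpoint` alternative (x = mean pixel offset of each segment) is
  available via `x_convention`.
* **Normalization.** Dividing the three filtered means by `m1` sets the
  basal segment to exactly 1, so the normalized slope `(m3 - m1)/(2 m1)` is
  invariant to any positive rescaling of the image — staining batch,
  exposure time, illumination, section thickness. This is the quantity the
  class signatures live on. Normalization is applied per line; a per-sample
  variant (normalizing pooled segment means) can be built from
  `filtered_mean()` directly, but per-line is the default because each line
  then contributes a self-contained, internally controlled replicate.
* **Regression mode.** The regression runs on the three filtered segment
  means by default (`segment_means`). Fitting all retained samples against
  their segment abscissa (`all_samples`) is available for sensitivity
  analysis; it weighs segments by retained-sample count and is not used for
  the reference signatures.

Per-line slopes are averaged per sample; per-sample means are the units of
all statistics (pooling lines across samples would pseudo-replicate).
Groups are summarised as mean ± SEM and compared with one-way ANOVA + Tukey
HSD (`stats::aov`, `stats::TukeyHSD`); the same histology class measured in
two cohorts is compared with a t-test — Welch by default, since equal
variances between institutions is an assumption nothing enforces; the
pooled-variance Student variant sits behind `var_equal = TRUE`.

A line whose basal filtered mean is not positive cannot be normalized; it
is flagged invalid, excluded and counted, never silently dropped.

### Threshold sweep

`threshold_sweep()` recomputes group mean normalized slopes on a 2% grid of
thresholds and reports a separation score per threshold: the minimum over
group pairs of `|difference of group means| / pooled SEM`. The score is a
reporting aid for judging where class signatures emerge (empirically, near
the top decile); the package never uses it to move the working threshold.
With zero within-group variance the score is `Inf` for distinct means and 0
for identical ones.

### Classification

`classify_sample()` assigns the nearest reference signature by absolute
distance in normalized-slope space and reports the margin to the runner-up;
margins below `delta` (default 0.04, about one reported SEM) are flagged
uncertain. The flag annotates, it never alters the numeric result.

## The phantom generator

`generate_phantom()` renders what the measurement assumes: an epithelial
band between a wavy basement curve and a surface curve, whose bright
(cytoplasmic) intensity at fractional height `h` steps through three
plateaus `c * B * (1 + s*(k-1))`, `k = seg(h)`; `B` is the basal plateau in
gray-value units, `s` the encoded normalized slope, `c` a global scale
factor standing in for institution-level staining/exposure differences.
Within each segment the basal 45% ramps smoothly (half-cosine) from the
previous plateau to the current one and the upper 55% dwells at the
plateau; the sub-basal level sits `s` below the basal plateau so that every
ramp spans exactly one segment step. Dark objects — nuclei as hard-zero
disks (radius 2.5-5 px, ~0.0039/px²) and larger glycogen patches (ellipses,
semi-axis 6-14 px, ~1e-4/px²) — cover about 20% of the band.
Multiplicative Gaussian noise (`noise_sd`, default 5% of local intensity)
is applied per pixel. Stroma below the basement sits at 12% of the basal
plateau; the region above the surface is nearly empty.

Annotation lines are vertical at integer columns with endpoints snapped to
integer rows, as in the original protocol of parallel vertical lines; the
sampler then reads exact pixel values, keeping the generator's calibration
analytic. Columns are screened so that every segment of every line has
under 45% dark-object cover and at least 13% of its samples artifact-free
on the plateau — the top-decile filter therefore always has plateau pixels
to find. Oblique and fractional-step lines remain fully supported by the
sampler and are tested against closed-form ramp oracles.

### Noise-selection calibration

Averaging the top decile of noisy samples is upward-biased: selecting the
largest fraction `f` of `N(mu, sigma)` draws yields mean
`mu + sigma * dnorm(qnorm(1-f))/f`. For the phantom design the eligible
pool per segment is the artifact-free dwell fraction, so
`f = 0.11 / (0.55 * (1 - 0.20)) = 0.25` and the bias factor at 5% noise is
`1 + 0.05 * 1.271 = 1.064`. The generated field is divided by this factor
(`kappa = 1` when noise is off), so measured filtered means recover the
nominal plateaus to within about 1% under default settings. Because every
segment shares the ramp-plus-dwell shape, any residual selection bias is a
common multiplicative factor that cancels exactly in the normalized slope
and nearly so in the raw slope. The constant derives from the design, not
from fitting any measured output.

### Presets and cohorts

Six presets encode the derivation-set signatures `s` = 0.37 / 0.19 / 0.02
and validation-set signatures 0.41 / 0.22 / 0.10, with default cohort sizes
13/18/12 and 34/16/18. Basal plateaus `B` = 8405.4 / 6021.1 / 7250.0 are
fixed by the ratio of the printed raw to normalized slopes (e.g.
3110/0.37); the validation presets reuse them under a global scale factor
0.55, which normalization must (and does) cancel. `generate_cohort()` adds
per-sample variation: `B` jittered ±10% (uniform), `s` jittered
multiplicatively with sd 8% of its value, thickness uniform in 270-330 px,
undulation amplitude 4-10 px. Multiplicative `s` jitter keeps `s >= 0`
naturally and scales between-sample spread with the class mean; an additive
jitter truncated at zero would bias the near-zero CIN III class upward.
The published between-sample SEMs reflect real biological heterogeneity on
top of measurement structure; phantom cohorts model only the latter, so
their between-sample spread is narrower than the clinical one — parameter
recovery, not population realism, is what they are for. Sample `i` uses
seed `base_seed + i` and the jitters are drawn under `base_seed`, so one
integer reproduces a cohort bit for bit.

### What phantoms do and do not show

Phantoms emulate the features the statistic must survive: a monotone
maturation gradient in segment plateaus, dark nuclei/glycogen objects,
intensity noise, geometric undulation, and global scale differences. They
do not emulate real chromatin texture, stromal autofluorescence structure,
inflammation, tangential sectioning, or focal lesions; passing recovery
tests therefore validates the computation and its invariances, not
clinical performance on slides.

## Numerical choices

* Nearest-rank percentile, ties kept at `>= threshold`: reproducible,
  oracle-checkable against `quantile(type = 1)`.
* Bilinear interpolation for line sampling: smooth, exact on planes, with
  trivial closed-form oracles; points outside the pixel hull raise an
  error instead of clamping silently.
* Degenerate inputs: constant images pseudo-color to the red end with a
  warning; identical groups report F = 0, p = 1; a single sample leaves the
  SEM `NA` and flagged; zero-basal lines are invalid-flagged.
* 32-bit float TIFF output is written by a minimal single-strip
  uncompressed writer (IEEE float sample format) and read back through
  libtiff; integer depths round-trip bit-exactly.
* Problem sizes: unit tests run on reduced phantom geometry (200x180 px,
  120 px thickness); the recovery suite and `scripts/acceptance.R` use the
  full default geometry (440x420 px, ~300 px thickness, 24 lines per image)
  at the stated cohort sizes.

## Known limitations

* Signatures are established for Normal, CIN I and CIN III; CIN II — a
  heterogeneous class that behaves like either neighbour — is out of scope.
* Lines are straight; strongly curved epithelium would need curvature-
  following sampling, which the package deliberately does not attempt.
* Stored image values are analysed as-is; any camera-side scaling applied
  before saving is invisible to (and cancelled by) basal normalization
  only if it is multiplicative.
* The CLI reads whole images into memory; whole-slide pyramidal formats
  are not supported.
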