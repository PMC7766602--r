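---
title: "Methods: quantifying pericapillary edema from NVC and CLSM images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pericapillary edema from NVC and CLSM images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capedema)
```

# Scope and data model

`capedema` quantifies pericapillary edema from two imaging modalities.
Nailfold video capillaroscopy (NVC) shows the first-row capillary loops of
the nailfold; short-term edema (histamine wheal, infusion load) blurs them
without changing their morphology. Confocal laser scanning microscopy (CLSM)
resolves the dermal papilla in cross-section — dark lumen, gray papilla,
bright melanin ring near the dermal–epidermal junction; here edema shows as
papilla hyporefractivity and, under venous occlusion, lumen dilation.

Images are `calibrated_image` objects: a non-negative double raster, a pixel
pitch in μm/px, and the source bit depth. Three conventions run through the
package:

* Coordinates are 0-based `(row, col)`; rectangles are half-open on the far
  side, so nested crops compose exactly.
* Intensities are never rescaled implicitly. An 8-bit image loads as values
  0–255, a 16-bit image as 0–65535. `normalize_unit()` is the explicit,
  logged conversion to `[0, 1]` (dividing by the nominal full scale; float
  rasters by their maximum).
* The pixel pitch is always user-supplied: neither TIFF nor PNG reliably
  carries acquisition geometry, and NVC camera pitch differs per
  magnification.

RGB inputs are reduced with fixed Rec. 709 luma weights (0.2126, 0.7152,
0.0722) rather than by channel guessing. Regions of interest interchange as
JSON/CSV rectangle lists or polygon vertex lists rasterized by the even-odd
rule; manual apical-diameter or perivascular-zone measurements are supported
only as landmark annotations (`measure_distance()`), since no detection
algorithm exists for them here.

# The sharpness score

The score is the mean absolute amplitude of a difference-of-Gaussians (DoG)
filtered image:

$$S(I) = \operatorname{mean}\,\bigl|\,G_{\sigma_\text{low}} * I -
G_{\sigma_\text{high}} * I\,\bigr|,$$

with defaults $\sigma_\text{low} = 0.5$ px and $\sigma_\text{high} = 8$ px.
The band-pass selects structures of roughly capillary width while removing
illumination gradients; epidermal water accumulation removes exactly this
fine-scale contrast, so $S$ falls as the image gets "foggy".

Numerical choices:

* Kernels are sampled Gaussians truncated at $4\sigma$ and renormalized to
  unit sum, so each blur preserves constants exactly and a constant image
  scores exactly zero (asserted to $10^{-12}$).
* Boundaries are handled by symmetric reflection. The kernel convention is
  narrow-minus-wide; the absolute value makes the sign irrelevant but the
  convention is fixed for reproducibility.
* The separable implementation is tested against a dense brute-force
  convolution to $10^{-10}$ absolute on random rasters.

$S$ is homogeneous of degree 1 in intensity: $S(aI) = aS(I)$. For this
reason sharpness is computed on the raw intensity scale by default, with
`normalize = TRUE` as the explicit opt-in for cross-acquisition comparisons.
Normalizing float rasters would divide by the raster maximum and silently
destroy the scaling property; comparisons across different bit depths,
gains, or illumination should either use a declared common scale
(`normalize_unit()` on integer data, where the divisor is the fixed full
scale) or — preferably — the relative-sharpness ratio, which cancels scale
entirely. The clinically meaningful quantities are relative anyway:
before/after ratios and time courses.

`relative_sharpness()` divides by the mean over a baseline window (default:
all pre-event points). `fit_timecourse()` fits a least-squares cubic
smoothing spline (`stats::smooth.spline`), with the smoothing level chosen
by generalized cross-validation when not supplied; `smoothing_factor = 0`
interpolates, other values are passed as `spar`. The fit reports the RMSE at
the observations, the location of the curve minimum over the observed span,
and the first post-minimum time at which the curve re-attains a stated
fraction (default 0.9) of the pre-event baseline. Degenerate (flat) series
are flagged rather than erroring, since clinical series may be short; a
step-like drop is smoothed by the spline, so an instantaneous drop factor is
better estimated from the first post-event observation than from the fitted
minimum.

# CLSM vessel size

A region drawn around a single capillary cross-section is smoothed with a
Gaussian (default σ = 15 px, or `smooth_um` converted via the pitch),
thresholded at 20% of the *smoothed* maximum, and the sub-threshold pixels
form the lumen candidate. The maximum is taken from the smoothed region —
the threshold is applied to smoothed pixels, which keeps the operation
self-contained and noise-robust; this is a deliberate reading of an
ambiguous rule. By default only the largest 8-connected component is kept,
so stray dark corners cannot inflate the area; exact ties are broken toward
the smallest centroid (row, then column) and flagged in
`component_policy_used`. Vessel size is $\sqrt{\text{area}}$, which is
proportional to an equivalent-circle diameter, so percent changes are
identical under either convention.

**Operating regime.** The relative threshold has a known geometric bias.
Where the frame maximum $M$ equals the intensity just outside the lumen, the
20% contour sits at depth $\approx 0.84\sigma$ inside the true edge (the
point where a blurred step falls to 0.2 of its plateau), eroding the radius;
if $\sigma$ is comparable to the lumen radius the lumen can disappear below
threshold entirely. Conversely, when the perilumen gray level is below
$0.2M$ the contour moves outside the edge and dilates the estimate. The
estimate is near-unbiased when $0.2M$ sits at the half-height of the lumen
edge — i.e. when the brightest structure in the region (the melanin ring) is
about 2.5× the perilumen (papilla) level, which is the configuration CLSM
actually presents. Consequently: smoothing must stay well below the lumen
radius (σ ≲ r/3), and the validation suite measures disks of radius
10–30 px with σ = 3 on phantoms with intensities (lumen 0, papilla 0.4,
ring 1.0), where the recovered $\sqrt{\text{area}}$ stays within 5% of
$r\sqrt{\pi}$. The σ = 15 default is kept for clinical-scale regions where
lumina are far larger than the smoothing kernel; users working at other
scales should set `smooth_sigma` (or `smooth_um`) accordingly.

# Papilla brightness

With pairwise-disjoint masks for papilla, melanin ring and lumen,

$$B = 100\,\frac{\overline{I}_\text{papilla}}
{\overline{I}_\text{ring} - \overline{I}_\text{lumen}}.$$

The ratio is invariant to multiplicative gain — absolute CLSM intensity
depends on depth, scanning power and tissue absorption — and covariant under
additive offset (only the numerator shifts), which the tests assert exactly
from the formula. A mean ring intensity at or below the mean lumen intensity
signals segmentation failure or a saturated frame and raises a
contrast-inversion error rather than returning a negative ratio. Masks are
supplied (manually segmented, or phantom ground truth); no automatic
papilla detector is provided. Cohort summaries flag groups with fewer than
10 tiles, reflecting the ~10–12 images per subject needed for a stable
estimate.

# Synthetic phantoms

The generator reproduces the statistical and optical structure the
estimators assume, with analytic ground truth:

* **Hairpin capillary** (`make_capillary_phantom`): a dark U-shaped tube
  (two limbs joined by a semicircular apex) on a bright background —
  nailfold morphology with edges at many orientations — rendered with 4×
  supersampled anti-aliased edges, then Gaussian-blurred (the edema model)
  and degraded with seeded additive Gaussian noise clipped to `[0, 1]`.
  Defaults: 256×256 frame, limb length 120 px, separation 40 px, tube width
  12 px, background 0.9, contrast 0.5 — proportions chosen to resemble a
  100× NVC loop filling most of a cropped region. The pre-blur tube is the
  ground-truth mask.
* **Papilla cross-section** (`make_papilla_phantom`): concentric lumen disk,
  papilla annulus, melanin ring and background with exact pixel-centre
  masks. Default intensities (0, 0.25, 1, 0.5) give a brightness ratio of
  exactly 25; `anti_alias = FALSE` produces the exact-mask phantom where the
  closed form holds to machine precision.
* **Effect pairs** (`make_effect_dataset`): before/after sets for the three
  calibration effects — occlusion dilation (radius × 1.10 by default),
  histamine hyporefractivity (papilla intensity × 0.80), histamine blur
  (σ 0.5 → 8). Magnitudes default to the observed clinical effect sizes
  (a ~10% median size increase under occlusion; a ~20% papilla-brightness
  decrease and a twofold sharpness drop under histamine); they are generator
  inputs, not claims. Per-pair radius jitter (σ 1.5 px) and 5% pixel noise
  emulate biological and detector variability.
* **Time course** (`make_timecourse`): baseline, instantaneous
  `drop_factor`-fold drop at the event, exponential recovery with constant
  τ, seeded Gaussian noise — the observed pattern of NVC sharpness after
  topical histamine.

All generators are bit-reproducible given their arguments and seed, and
restore the caller's RNG state. What the phantoms deliberately do **not**
model: speckle and multiplicative noise, light transport in layered skin,
erythema/color, multiple capillary rows, motion artifacts, or mosaic
stitching. Passing the validation suite therefore shows the estimators are
correct and stable under the stated image model — not that clinical images
meet that model; segmentation quality on real CLSM remains the user's
responsibility.

# Group statistics

`kruskal_wallis()` computes the tie-corrected H with a χ² reference
(k − 1 df). For very small studies (total n ≤ 10) it switches to an exact
permutation p-value by enumerating every assignment of the pooled values to
groups of the observed sizes — the enumeration is tested against an
independent brute-force oracle. All pooled values identical is reported as a
degenerate comparison with p = 1 rather than an error. The pairwise
follow-up is two-sided Mann–Whitney with Bonferroni adjustment
(`min(1, m·p)` over the m pairs) — the most common reading of
"Kruskal–Wallis with Bonferroni correction" in clinical reports — with
Dunn's rank z-test available via `method = "dunn"`. Stars follow the
conventional strict thresholds (0.05, 0.01, 0.001, 0.0001). Box summaries
use type-7 (linear interpolation) quartiles and whiskers at the most extreme
points within 1.5 IQR of the quartiles.

A statistical caveat mirrored from practice: capillary-level measurements
within a subject are treated as independent observations, as is common in
these study designs. Where subjects contribute many capillaries each, a
mixed model would be more defensible; that is out of scope here.

# Batch pipeline and validation

`run_study()` processes a manifest (image, subject, condition, annotation,
pitch, metric) into one tidy row per image × metric × ROI, box summaries per
condition, pairwise comparisons, and percent change of medians. Per-record
failures are collected into an error report while the run continues —
clinical batches tolerate partial annotation — and only a fully failing
manifest is an error.

`run_validation(seed)` regenerates every phantom dataset and checks the
package's load-bearing properties: blur monotonicity of the sharpness score
over σ ∈ {0.5, 3.8, 7.2, 11, 14, 17}, the exact null and degree-1
homogeneity, separable-vs-dense DoG agreement, vessel-size recovery (radii
10–30 px, within 5%), the papilla-brightness closed form and gain
invariance, recovery of the generated +10% dilation and −20%
hyporefractivity (within ±3 points, with a significant Bonferroni-adjusted
pairwise test), time-course minimum and recovery localization, the
Kruskal–Wallis type-I rate at α = 0.05 (binomial 99% interval), and
exact-vs-brute-force agreement of the permutation branch. Report bodies
contain no timestamps, so two runs with the same seed are byte-identical.

Problem sizes throughout (256² and 201² rasters, 12–20 effect pairs, 60-point
time series, 1000-replicate type-I simulation) were chosen so the entire
suite runs in well under a minute per property on a single CPU while keeping
Monte-Carlo intervals tight enough for the stated tolerances.

# Known limitations

* No automatic capillary or papilla detection; ROIs and masks are inputs.
* No video decoding (time courses are frame directories), no CLSM mosaic
  stitching, no z-stack analysis, no DICOM.
* The sharpness score is a relative quantity; its absolute units are
  arbitrary and should only be compared within a declared intensity scale.
* The vessel-size estimator inherits the relative-threshold bias analysed
  above; report the smoothing scale alongside results.
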