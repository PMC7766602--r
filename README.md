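# capedema

Quantitative assessment of pericapillary edema from nailfold video
capillaroscopy (NVC) and reflectance confocal laser scanning microscopy
(CLSM) images.

## The problem

Fluid accumulation in the interstitial space around skin capillaries has no
routine quantitative readout: clinicians mostly grade edema by physical
examination. Two optical signatures make it measurable. In NVC, short-term
edema does not change capillary morphology but blurs the image — capillaries
take on a "foggy" appearance as water accumulates in the viable epidermis and
flattens the refractive-index contrast. In CLSM cross-sections of the dermal
papilla, the capillary lumen is dark, the papilla gray and the melanin-rich
basal zone bright; edema makes the papilla hyporefractive (darker) and can
dilate the lumen.

`capedema` implements the three estimators that turn these signatures into
numbers, a nonparametric statistics layer for before/after and multi-group
designs, and a synthetic phantom generator with analytic ground truth so the
whole pipeline can be validated end to end. It is aimed at researchers
analysing microcirculation imaging studies (venous occlusion and histamine
challenge experiments, infusion monitoring, heart-failure cohorts).

## The estimators

**NVC image sharpness.** A difference-of-Gaussians band-pass filter
(σ_low = 0.5 px, σ_high = 8 px, reflective boundaries) isolates small
high-contrast structure such as first-row capillary loops; the sharpness
score is the mean absolute amplitude of the filtered image,

S(I) = mean |G(σ_low) ∗ I − G(σ_high) ∗ I|.

S is zero for constant images, homogeneous of degree 1 in intensity, and
decreases monotonically as the image is blurred. Time courses of S are
fitted with a least-squares cubic smoothing spline to locate the post-event
minimum and the recovery time.

**CLSM vessel size.** A region drawn around one capillary cross-section is
Gaussian-smoothed (default σ = 15 px) and thresholded at 20% of the smoothed
maximum; the largest 8-connected sub-threshold component is the lumen, and
vessel size is √area (px, or μm via the pixel pitch).

**CLSM papilla brightness.** With manual (or phantom ground-truth) masks of
papilla, melanin ring and lumen,

B = 100 · mean(papilla) / (mean(ring) − mean(lumen)),

a ratio invariant to detector gain, so values are comparable across frames,
depths and scanning intensities.

**Statistics.** Kruskal–Wallis omnibus (tie-corrected, exact permutation
p-value for very small totals) with Bonferroni-corrected pairwise
Mann–Whitney follow-up (Dunn's test optional), significance stars at
0.05/0.01/0.001/0.0001, box summaries with 1.5 IQR whiskers, and percent
change of medians as the effect measure.

## Worked example

Score a simulated capillary under increasing blur, then recover a generated
20% papilla-brightness drop:

```r
library(capedema)

sigmas <- c(0.5, 3.8, 7.2, 11, 14, 17)
dplyr::bind_rows(lapply(sigmas, function(s) {
  ph <- make_capillary_phantom(blur_sigma = s)
  dplyr::mutate(sharpness(ph$image), blur_sigma = s, .before = 1)
}))
#>   blur_sigma roi   sigma_low sigma_high sharpness
#> 1        0.5 <NA>        0.5          8   0.0266
#> 2        3.8 <NA>        0.5          8   0.0164
#> 3        7.2 <NA>        0.5          8   0.00936
#> 4       11   <NA>        0.5          8   0.00478
#> 5       14   <NA>        0.5          8   0.00284
#> 6       17   <NA>        0.5          8   0.00184
```

The sharpness score falls monotonically (14-fold over this blur series):
stronger epidermal blur, lower score.

```r
hypo <- make_effect_dataset("histamine_hyporefractivity", n_pairs = 12, seed = 1)
vals <- dplyr::bind_rows(lapply(seq_len(nrow(hypo)), function(i) {
  tibble::tibble(
    condition = c("before", "after"),
    value = c(papilla_brightness(hypo$before[[i]]$image, hypo$before[[i]]$segmentation)$value,
              papilla_brightness(hypo$after[[i]]$image,  hypo$after[[i]]$segmentation)$value))
}))
brightness_cohort_summary(vals)
#>   condition  n median   q1   q3 low_n
#> 1 before    12   26.8 26.7 26.8 FALSE
#> 2 after     12   21.5 21.5 21.6 FALSE
#>   percent change of medians: -19.61%

pairwise_bonferroni(vals, value, condition)
#> <comparison_result> Kruskal-Wallis H = 17.28, p = 3.226e-05 (chi-squared)
#>   group1 group2     raw_p adjusted_p stars
#> 1 before after  0.0000366  0.0000366 ****
```

The generated 20% hyporefractivity comes back as a −19.6% change of medians,
highly significant — the pipeline recovers the effect it was built to
detect. `run_study()` applies the same flow to a manifest of image files on
disk, and `run_validation(seed)` reruns the complete synthetic validation
suite. A thin command-line wrapper lives at `inst/cli/capedema.R`.

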