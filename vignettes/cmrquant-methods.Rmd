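---
title: "Quantifying enhanced myocardial lesions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enhanced myocardial lesions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cmrquant)
```

## The measurement problem

After an acute myocardial infarction, contrast-enhanced cardiac MR shows the
injured myocardium as a region of altered signal on short-axis slices:
hyperintense under late gadolinium enhancement (LGE, gadolinium retained in
nonviable tissue), hypointense under manganese-enhanced MRI (MEMRI, Mn2+
taken up only by viable cardiomyocytes) and hypointense under iron-oxide
nanoparticle MRI (MNP, T2* dropout where phagocytosing macrophages
accumulate). The quantity of interest is the *enhancement size*: the extent
of the enhanced lesion as a percentage of the left-ventricular (LV)
myocardium. Because inflammatory cells concentrate in the peri-infarct
border zone, the inflammation read-out is expected to exceed the infarct
read-out in the acute phase, and the two should be positively correlated.

`cmrquant` implements this measurement as a reproducible, observer-free
pipeline, together with the statistics used to compare modalities and
measurement methods, and a synthetic phantom generator that provides ground
truth for validation.

## Per-slice quantification

Given a slice and its annular myocardial region of interest (ROI), the
estimator proceeds in three steps.

**Normalisation.** Myocardial intensities are min-max normalised over the
ROI only: $v' = (v - \min v)/(\max v - \min v)$, so every ROI histogram
spans exactly $[0, 1]$ and is invariant to affine intensity scaling (which
also makes the pipeline indifferent to whether an image arrives as float
NIfTI or integer TIFF/PNG). A constant ROI cannot be normalised; it is
flagged degenerate, all values are set to 0.5, and segmentation returns an
empty lesion with a warning.

**Otsu's threshold.** The normalised ROI values are binned into a 256-bin
histogram on $[0, 1]$ (the 8-bit convention; the bin count is a tunable
`n_bins`). For every inter-bin boundary $t$ the between-class variance

$$\sigma_b^2(t) = \omega_0(t)\,\omega_1(t)\,\big(\mu_0(t) - \mu_1(t)\big)^2$$

is evaluated from cumulative histogram moments, where $\omega_i$ and
$\mu_i$ are the weight and mean of the classes below/above $t$. Maximising
$\sigma_b^2$ is equivalent to minimising the total within-class variance
(the identity $\sigma_b^2(t) + \sigma_w^2(t) = \sigma^2$ holds at every
candidate and is asserted in the tests). The threshold is reported at the
upper edge of the last below-class bin.

**Geometric read-out.** Three read-outs of lesion extent are available:

* *area-based*: enhanced pixels / ROI pixels x 100. "Enhanced" means
  strictly above the threshold for hyperenhancing modalities and strictly
  below it for hypoenhancing ones; threshold-coincident pixels always join
  the below class.
* *sector-based*: every ROI pixel is assigned to the 1-degree radial sector
  $\lfloor \theta \rfloor$ of its centre angle around the LV centre
  (half-open bins), the per-sector mean normalised intensity is thresholded
  with Otsu on a 64-bin histogram, and the read-out is enhanced sectors /
  valid sectors x 100. Sectors containing no myocardial pixel are excluded
  from both numerator and denominator. The sector geometry makes the
  read-out robust to wall-thickness variation.
* *midline length-fraction*: the mid-wall circle — per angle, the midpoint
  radius between the inner and outer myocardial boundary crossings along
  that ray — is sampled at 3600 angles, and the read-out is the percentage
  of myocardium-hitting samples that land in a lesion mask. This is the
  mask-level analog of histological length-based infarct sizing; since the
  original histological procedure is not precisely specified anywhere we
  could follow, this definition is one reasonable reading and is documented
  as such. It needs a lesion *mask* rather than an image, so in practice it
  is applied to ground-truth (or histology-derived) masks.

### Conventions and numerical choices

* Coordinates are 0-based with x = column, y = row and pixel centres at
  integer positions; angles measure 0 degrees along +x, increasing with +y,
  and all modules share this convention (an `angle_offset` rotates the
  sector frame for anatomical alignment).
* Contours rasterise by the even-odd rule on pixel centres, with centres
  that lie exactly on a contour edge counting as inside. This makes
  rasterisation exactly checkable against an independent point-in-polygon
  oracle.
* The LV centre is the endocardial-polygon centroid when contours are
  available, otherwise the centroid of the cavity (the enclosed background
  component of the mask, found by flood fill from the image border); if no
  cavity exists the mask centroid is used with a warning.
* Otsu ties are broken toward the smallest maximising candidate, for
  determinism. One visible consequence: for a perfectly separated bimodal
  ROI the variance curve is flat across the empty gap between the modes, so
  the threshold sits at the gap's lower edge. Classification is unaffected.
* The sector-level Otsu uses 64 bins because there are at most 360 sector
  values; 256 bins would be mostly empty and invite tie artifacts.
* More than 25% empty sectors aborts the sector read-out (the centre is
  almost certainly outside the cavity); a mid-wall radius undefined at more
  than 10% of angles aborts the midline read-out.

## The synthetic phantom study

No raw images from the animal study design this package targets are
publicly deposited, so validation rests on a synthetic short-axis phantom
with known truth. One phantom is an annulus (default endocardial radius 40
px, epicardial 60 px on a 256x256 grid, mirroring a 30 mm field of view at
256 matrix) carrying wedge lesions described by start angle, angular span
and transmurality (wall-thickness fraction, measured from the endocardium
outward). Three intensity levels paint background, myocardium and lesion;
Rician noise — the magnitude of the signal plus complex Gaussian noise,
$\sqrt{(v+n_1)^2 + n_2^2}$ with per-channel SD `noise_sigma` — is applied
last, because magnitude MR images are Rician, not Gaussian. Ground-truth
masks are taken before noise. The analytic truth values are
`true_fraction_area` (lesion pixels / annulus pixels) and
`true_fraction_angle` (union of wedge spans / 360); for transmural wedges
the two coincide up to rasterisation.

A *study* (`study_spec()`/`generate_study()`) emulates a cohort: by default
14 subjects x 4 slices x 3 modalities (LGE hyper; MEMRI, MNP hypo), the
slice count matching the slices below the mid-ventricular level in the
emulated design. Subject-level wedge spans are drawn per modality from a
Gaussian copula with pairwise correlation `cross_modality_rho` (default
0.5), clamped to [1, 360] degrees — clamping rather than
rejection-truncation keeps the sampler a fixed-length function of the seed,
and clipping is negligible at the default means. All modalities of a
subject share one wedge centre angle (they image the same physical lesion);
the inflammation modality's wedge is widened by `border_margin_deg` per
side (default 15 degrees, our free parameter for the border zone — no
quantitative border-zone width is available to match). A per-slice span
perturbation (SD 10 degrees), shared across modalities within a slice,
emulates apex-to-base variation of lesion extent and gives per-slice
scatter.

The default span distributions (LGE 147 +/- 42, MEMRI 159 +/- 54, MNP 176
+/- 36 degrees, before the border margin) were chosen once so that
transmural span/360 lands the per-slice enhancement percentages in the
ranges typical for these mechanisms in acute murine infarcts (infarct
around 41-44%, inflammation around 57% after widening). Contrast defaults
place myocardium and lesion at 0.5 -/+ 0.2 (absolute contrast 0.4) with
`noise_sigma = 0.05`.

**What the phantom does not emulate** — and hence what passing tests do not
show about real data: partial-volume and blooming artifacts (iron oxide in
particular blooms), contrast kinetics and washout timing, wall-motion or
morphological change between imaging days, intensity inhomogeneity, papillary
muscles, manual-tracing variability, and non-wedge lesion shapes. The
phantom validates the *geometry and statistics* of the measurement, not the
imaging physics.

## Statistics

`bland_altman()` (bias = mean difference; limits of agreement = bias +/-
1.96 x sample SD of differences), `correlate()` (Pearson, and Spearman as
Pearson on midranks; two-sided p from the $t$ transform on $n-2$ df; Fisher
z 95% CI for Pearson) and `linear_fit()` (closed-form OLS with the
pointwise confidence band of the mean response) are implemented from their
closed forms and cross-checked in the tests against `cor.test()` and
`lm()`. The modality comparison is a one-way repeated-measures ANOVA
computed from its sums-of-squares decomposition with the slice as the
repeated unit (each slice is imaged by every modality), Tukey's
studentised-range contrasts on the within-unit error term, and a
Shapiro-Wilk normality check of the within-unit residuals reported
alongside (delegated to `stats::shapiro.test`). Because slices within a
subject are not independent, `subject_level = TRUE` first averages slices
within subject and uses the subject as the unit; the per-slice analysis is
the default because the emulated design reports per-slice points. Both
Pearson and Spearman are always reported rather than auto-selected on the
normality result, which is printed next to them.

## Validation problem sizes

The test-suite and acceptance-script checks run at sizes chosen to give
tight Monte-Carlo noise while staying desk-scale: 100 random histograms for
the Otsu oracle equivalence; 20 noiseless wedge geometries with spans 30-300
degrees (recovery within 1.5 / 1.0 / 1.0 percentage points for area /
sector / midline, and Bland-Altman bias between the geometric read-outs
within 1 point); 50 noisy phantoms at `noise_sigma = 0.05`, contrast 0.4
(mean absolute error within 3 points); 1000 within-unit label permutations
for the F-test calibration; and the full default 14-subject study for the
qualitative design pattern (inflammation read-out significantly larger than
both infarct read-outs, positively correlated with them — at 14 subjects
the sample correlation itself is a noisy estimate of the copula's rho, so
only its sign is asserted).

## Limitations

Beyond the phantom realism caveats above: the package does not segment the
myocardium from raw images (contours or masks are inputs); only two-class
Otsu is provided (no FWHM or n-SD thresholding alternatives, no multi-level
Otsu); sector values use the mean of member pixels (a maximum-based variant
would weight small bright cores differently; the mean is the stable default
matching smooth radial profiles); DICOM and vendor raw formats are out of
scope. Exact numeric reproduction of any particular published per-case
threshold is impossible without the underlying raw images, since the
histogram bin count and normalisation window of the original interactive
analyses are not recoverable.
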