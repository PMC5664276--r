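# cmrquant

Observer-free quantification of enhanced myocardial lesions on short-axis
contrast-enhanced cardiac MR, with the statistics used to compare imaging
modalities and measurement methods, and a synthetic phantom study generator
that supplies ground truth for validation.

## The problem

After an acute myocardial infarction, three contrast mechanisms show the
injury on cardiac MR: late gadolinium enhancement (LGE) renders nonviable
myocardium **hyperintense**, manganese-enhanced MRI (MEMRI) renders it
**hypointense** (Mn²⁺ enters only viable cardiomyocytes), and iron-oxide
nanoparticle MRI (MNP) renders the **inflamed** region hypointense
(macrophage T2\* dropout). The read-out in all three cases is the
*enhancement size*: the enhanced lesion extent as a percentage of the LV
myocardium. Manual windowing is observer-dependent, so the lesion is
segmented by Otsu's histogram threshold — the intensity distribution of the
myocardial ROI is bimodal (enhanced vs non-enhanced), and Otsu's method picks
the threshold *t* maximising the between-class variance

σ²_b(t) = ω₀(t)·ω₁(t)·(μ₀(t) − μ₁(t))²,

equivalently minimising the within-class variance, over the 256-bin
histogram of min-max-normalised ROI intensities. Enhancement size is then
measured geometrically in two ways:

* **area-based** — enhanced pixels / myocardial pixels × 100;
* **sector-based** — the myocardium is registered to 360 radial sectors of
  1° around the LV centre, sector mean intensities are Otsu-thresholded
  (64 bins), and the read-out is enhanced sectors / valid sectors × 100.

A third read-out, the **midline length-fraction** (percentage of the
mid-wall circle falling inside a lesion mask), is the mask-level analog of
histological length-based infarct sizing.

Method agreement and modality comparisons use Bland–Altman analysis,
Pearson/Spearman correlation, ordinary least squares, and repeated-measures
one-way ANOVA with Tukey contrasts (Shapiro–Wilk normality check reported
alongside).

Because no raw images of the emulated animal-study design are publicly
available, the package ships a seeded phantom generator: annular LV
myocardium with transmural wedge lesions, Rician magnitude noise, an
inflammation wedge widened by a border-zone margin, and controllable
cross-modality lesion-size correlation — so every estimate can be checked
against analytic ground truth. See the methods vignette
(`vignettes/cmrquant-methods.Rmd`) for the full model and design notes.

## Worked example

Quantify one noisy phantom slice with a 120° transmural wedge (true extent
120/360 = 33.3%):

```r
library(cmrquant)

ph <- generate_phantom(phantom_spec(wedges = lesion_wedge(start_angle = 210, span = 120),
                                    noise_sigma = 0.05, seed = 42))
q <- quantify_slice(ph$image, ph$truth$myocardium_mask, polarity = "hyper")
q
#> <lesion_quant> subject=NA modality=NA slice=NA polarity=hyper
#>   area     33.31 %  (threshold 0.426, 2092 / 6280 pixels)
#>   sector   33.33 %  (threshold 0.281, 120 / 360 sectors)
ph$truth$true_fraction_area
#> [1] 33.31
```

Both geometric read-outs recover the true lesion fraction; the thresholds
differ because the pixel-level and sector-level histograms differ, but the
classification does not. A full 14-subject study (4 slices × 3 modalities
each, inflammation wedge 15°/side wider than the infarct wedge):

```r
spec <- study_spec(n_subjects = 14, seed = 1)
st <- generate_study(spec)
pol <- setNames(spec$modalities$polarity, spec$modalities$name)
rois <- lapply(st$truths, function(t) myocardial_mask(t$myocardium_mask))
tab <- quantify_study(st$images, rois, pol, methods = c("area", "sector"))
compare_study(tab)
#> == Modality comparison (area-based) ==
#> Repeated-measures ANOVA (slice as unit, n = 56):
#>   LGE        41.4 +/- 11.6 %
#>   MEMRI      46.6 +/- 16.9 %
#>   MNP        58.5 +/- 8.9 %
#>   F(2, 110) = 83.967, p = 7.241e-23 (Shapiro-Wilk residual p = 0.000603)
#>   Tukey contrasts:
#>     MEMRI - LGE      diff =    5.22, p_adj = 0.0005526
#>     MNP - LGE        diff =   17.07, p_adj = 9.881e-15
#>     MNP - MEMRI      diff =   11.86, p_adj = 1.104e-13
#> ...
#> == Method agreement: area vs sector ==
#>   [pooled] Bland-Altman (n = 168): bias = 0.006, limits of agreement [-0.225, 0.237]
#> ...
#>   [area:LGE_vs_MNP]
#>     Pearson correlation (n = 56): r = 0.7705, p = 3.827e-12, 95% CI [0.6365, 0.8593]
```

The inflammation modality (MNP) reads significantly larger than both infarct
modalities, the two geometric methods agree with negligible bias, and
infarct and inflammation extents correlate positively — the qualitative
pattern the synthetic design encodes.

The same workflow is scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/cmrquant.R simulate --out-dir out --seed 1
Rscript inst/cli/cmrquant.R quantify --out-dir out --seed 1
Rscript inst/cli/cmrquant.R compare  --out-dir out --seed 1
```

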