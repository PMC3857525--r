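# wmhseg — semi-automated white-matter-hyperintensity segmentation

White matter hyperintensities (WMH) are bright regions in cerebral white
matter on FLAIR MRI, associated with small-vessel disease, cognitive
decline and dementia risk. Measuring the WMH load per subject usually means
either hours of manual tracing or complex multi-spectral classifiers.
`wmhseg` implements a middle road for researchers and clinical labs: a
fully scriptable pipeline that segments WMH on FLAIR alone with a single
global intensity threshold,

    threshold = mean + k · SD        (k = 1.5 by default)

computed over all brain voxels of the preprocessed image, followed by
deterministic merging of manual edit masks and volumetry in cm³. The
package also ships the full agreement battery used to validate such
pipelines against manual raters — Dice similarity coefficient (DSC),
paired *t*-tests, Pearson/Spearman correlation, linear regression — and a
synthetic 3-D brain phantom generator with exact ground truth, so the whole
chain is testable without any real MRI.

The pipeline stages: brain-mask construction by summing GM/WM/CSF tissue
maps; affine FLAIR→T1 coregistration and T1→template normalisation
(correlation-ratio cost, multi-resolution simplex optimisation, FLIRT-style
behaviour); removal of a cerebellum/brainstem exclusion mask; 2 mm FWHM
Gaussian smoothing; thresholding; volumetry. Images are NIfTI-1
(`.nii`/`.nii.gz`), transforms are 4×4 text matrices.

## Worked example

Everything below runs from a synthesised phantom — no data download.

```r
library(wmhseg)

ph  <- generate_phantom(phantom_spec())      # FLAIR+T1+truth, 96x96x60
pre <- preprocess_pipeline(ph$flair, ph$t1, ph$tissues,
                           ph$template, ph$exclusion_mask)
seg <- threshold_segment(pre$flair, pre$mask, k = 1.5)
seg
#> <wmh_segmentation>
#>   brain voxels: 132689, intensity 87.23 +/- 26.42
#>   threshold: mean + 1.5 * SD = 126.852
#>   lesion: 6362 voxels = 6.362 cm^3
score_against_truth(seg$lesion_map, ph)[c("dsc", "volume_error_cm3")]
#> $dsc
#> [1] 0.9801816
#> $volume_error_cm3
#> [1] 0.059
```

The printed report says: ~133k voxels entered the intensity statistics,
the global threshold landed at 126.9 (between the phantom's WM mean of 100
and lesion mean of 160), and the segmented load is 6.36 cm³ against a true
6.30 cm³ — a spatial overlap (DSC) of 0.98, far above the conventional 0.7
bar for good agreement.

Comparing methods on per-subject volume tables (here the bundled
30-subject reference tables of two manual raters vs the pipeline):

```r
tab <- read_volume_table(wmh_example_table("table1"))
dsc <- read_volume_table(wmh_example_table("table2"))
agreement_report(tab, dsc = dsc)
#> <wmh_agreement> n = 30 subjects
#>
#> Lesion volumes (cm^3):
#>   rater1           mean  16.74  SD  13.89
#>   rater2           mean  19.50  SD  16.29
#>   semi_automated   mean  18.63  SD  14.81
#>
#> rater1 vs semi_automated:
#>   paired t = -1.790 (df 29, p = 0.0839)
#>   Pearson r = 0.921 (r^2 = 0.847), Spearman rho = 0.949
#>   OLS: slope 0.982, intercept 2.201, F(1,28) = 155.547
#> ...
```

Manual and semi-automated volumes do not differ significantly (paired t,
df 29), correlate at r ≈ 0.92–0.97, and overlap spatially at mean DSC
0.77–0.78.

A command-line front end wrapping the same functions is installed at
`inst/cli/wmhseg.R` with subcommands `phantom`, `preprocess`, `segment`,
`evaluate` and `run` (batch mode with per-subject failure isolation).

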