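---
title: "Semi-automated WMH segmentation: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated WMH segmentation: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhseg)
```

## The problem and the method

White matter hyperintensities (WMH) appear as bright regions in cerebral
white matter on FLAIR MRI and are a marker of small-vessel disease,
cognitive decline and dementia risk. Quantifying them by hand is accurate
but slow (hours per subject) and rater-dependent. `wmhseg` implements a
deliberately simple, reproducible alternative: after standardised
preprocessing, WMH are segmented by a single global intensity threshold on
the FLAIR histogram,

$$\tau = \mu + k\,\sigma, \qquad k = 1.5 \text{ by default},$$

where $\mu$ and $\sigma$ are the mean and sample SD of all brain voxel
intensities. A voxel is lesion if its intensity is at or above $\tau$.
Residual errors are corrected by deterministic *edit masks* (voxels to add,
voxels to remove) rather than interactive editing, so a full analysis is
scriptable and exactly repeatable. Lesion load is the voxel count times the
voxel volume.

The pipeline stages mirror standard FSL/SPM practice:

1. **Brain mask** — the GM, WM and CSF maps from a unified tissue
   segmentation are summed and binarised at 0.5 (majority probability).
   Tissue segmentation itself is *not* reimplemented: the maps are inputs
   (the phantom generator supplies ground-truth maps for testing).
2. **Coregistration** — the FLAIR is aligned to the T1 by an affine
   transform maximising a correlation-ratio similarity.
3. **Spatial normalisation** — the skull-stripped T1 is registered to a
   user-supplied template; the composed FLAIR-to-template transform is
   applied to the skull-stripped FLAIR in a *single* trilinear resample, so
   the image is interpolated only once.
4. **Exclusion** — a template-space mask of cerebellum and brainstem
   (regions where WMH are rare and FLAIR artifacts common) is removed.
5. **Smoothing** — 2 mm FWHM Gaussian filtering suppresses residual
   inhomogeneity. Intensity statistics are computed after smoothing.

## Why a global threshold at mean + 1.5 SD works

The threshold only separates lesions when the brain histogram is wide
enough that $\mu + 1.5\sigma$ falls between the WM intensity and the lesion
intensity. This is not an accident of tuning: the brain mask from a tissue
segmentation contains a substantial CSF fraction (ventricles plus sulcal
CSF, typically 15–25% of brain volume), and CSF is nearly dark on FLAIR.
That dark mass pulls $\mu$ down and widens $\sigma$, placing
$\mu + 1.5\sigma$ near the WM/lesion boundary midpoint. On the default
phantom (CSF fraction 14%) the threshold lands at ≈127 for WM at 100 and
lesions at 160 — almost exactly the edge midpoint of 130, which minimises
partial-volume miscounting on the smoothed image. A phantom with
unrealistically little CSF (a few percent) narrows the histogram, drops the
threshold to ≈115, and inflates the segmented volume by >20% through the
blurred lesion halo; we document this because it delineates the method's
operating envelope: the threshold rule presumes whole-brain statistics,
CSF included.

Two conventions are made explicit because the rule is sensitive to them:

* **"All brain voxels"** means the in-mask voxels of the smoothed,
  normalised image when a mask is supplied, and the strictly positive
  voxels otherwise — exact zeros are background introduced by
  skull-stripping and would corrupt both moments.
* **Boundary rule** — a voxel exactly at $\tau$ is lesion
  (keep-at-threshold), matching common thresholding tools.
* **SD denominator** is $N-1$ (sample SD), configurable to $N$; at brain
  voxel counts the difference is negligible but the choice is surfaced.

## Registration

`register_affine()` estimates a world-to-world affine (6 or 12 degrees of
freedom) by derivative-free simplex optimisation of a correlation-ratio
cost, coarse-to-fine over a 3-level image pyramid (downsampling factors 4,
2, 1), starting from intensity centre-of-mass alignment, with rotations and
scalings parameterised about the fixed image's centre of mass. Three
numerical choices matter:

* The correlation ratio is computed over the *whole* fixed grid with the
  zero background as a dedicated bin (32 intensity bins for the
  foreground). Restricting the cost to the support overlap lets the
  optimiser inflate the scale a few percent to keep edge partial-volume
  voxels out of the evaluation; with the background bin the cost has a
  sharp minimum at the true transform (verified by parameter-recovery
  tests: translations recovered to ≤0.25 mm and rotations to ≤0.4° over
  ten random rigid transforms, scale to <0.5%).
* For 12-dof registration the rigid parameters are estimated first at the
  coarser levels, then all 12 are opened up. The full-resolution level is a
  polish: the simplex is restarted (it re-expands from its collapsed
  state) for up to three rounds of 300 iterations, stopping when the cost
  stops moving — plain Nelder-Mead tends to collapse prematurely in 6–12
  dimensions, and the restarts recover the last fraction of a degree.
* The starting and achieved costs are compared on the finest level; if
  optimisation ever ends worse than the centre-of-mass start (it should
  not, but the guarantee is cheap), the start is returned.

## The synthetic phantom

`generate_phantom()` builds the complete input set — FLAIR, T1,
ground-truth tissue maps, brain mask, exclusion mask, template, lesion
ground truth — so every stage is testable without real MRI. The anatomy is
concentric ellipsoids: a sulcal CSF rim (outer 4% of the cerebral radius),
a GM shell, a WM core, two enlarged CSF ventricles, and an inferior
"cerebellum/brainstem" block flagged by the exclusion mask. Default FLAIR
intensities are CSF 30, GM 90, WM 100, lesion 160 (arbitrary units) with
independent Gaussian noise of SD 5 (5% of the WM mean) added inside the
brain; the T1 uses CSF 30, GM 70, WM 110 so the two contrasts are genuinely
different and coregistration is a real cross-modal problem. The template is
the noise-free T1, making normalisation a near-identity problem by default;
registration stress tests inject known transforms through
`true_flair_to_t1`, which displaces the synthesised FLAIR so that
registration must recover the injected motion.

The default lesion set is two confluent periventricular caps plus one small
deep WM lesion, 6.3 cm³ in total (≈4.5% of the phantom brain). This
emulates the moderate-to-high-load, confluent-lesion phenotype typical of
elderly cohorts with appreciable WMH burden (per-subject loads of a few to
several tens of cm³). Lesions are specified explicitly in mm (no random
lesion sampler), so the ground-truth voxel count is exactly constructible
rather than estimated; the generator errors if any lesion voxel falls
outside the WM compartment.

What the phantom does *not* emulate, and what passing tests therefore do
not show about real data: bias fields, Rician noise (Gaussian is used —
at this SNR the difference is negligible for thresholding, and Gaussian
keeps tail arithmetic transparent), FLAIR-specific artifacts (septum
pellucidum brightness, fourth-ventricle flow artifacts) that drive false
positives in practice, graded lesion edges, and anatomical variability.
The editing step (`apply_edits()`) exists precisely because real data
contain such structure; on the phantom it is exercised only as set
arithmetic.

## Agreement evaluation

`agreement_report()` reproduces the standard validation battery between
segmentation methods: per-method volume means and SDs, paired two-tailed
Student's *t*-tests on per-subject volumes (df = n − 1), Pearson *r* and
*r*², Spearman rank correlation, ordinary least squares of one method's
volumes on the other's, and Dice similarity coefficient (DSC) summaries.
DSC = 2|A∩B|/(|A|+|B|); 0.7 is the conventional bar for good agreement
between delineations. Two degenerate-input conventions: when both masks
are empty the DSC is defined as 1 (agreement on absence) with a loud
warning, since the ratio is 0/0; a paired *t*-test on identical columns
raises a degenerate-input error rather than returning 0/0. For a
regression of n paired volumes the report carries the computed F with
df = (1, n − 2).

The package ships a 30-subject reference table of per-subject lesion
volumes (two manual raters and the semi-automated pipeline) and the
corresponding pairwise DSC table (`wmh_example_table()`); the test suite
asserts that the full battery reproduces that table's published summary
statistics at their printed rounding.

## Problem sizes and tolerances used in the tests

The default phantom grid is 96 × 96 × 60 at 1 mm isotropic; unit and
property tests use 64 × 64 × 40 and smaller grids, and the
contrast-response suite uses 48 × 48 × 32 — the anatomy scales with the
grid, so these are the same brain at lower resolution. Registration
parameter recovery is asserted at 0.5 mm / 0.5° over ten random rigid
transforms (translations in ±5 mm, rotations in ±5°); NIfTI round trips at
1e−5 of the data range (float32 storage); threshold arithmetic identities
exactly. The phantom end-to-end bar is DSC ≥ 0.7 with |volume error| ≤ 15%
— on the default phantom the pipeline achieves DSC ≈ 0.98 and volume error
under 1%, so the bars are met with a wide margin rather than at their
edges.

## Known limitations

* A single global threshold cannot separate lesions whose intensity
  overlaps the upper tail of normal tissue; the method's own answer is the
  edit step, not a smarter classifier (tissue-class models, MRF/k-NN/fuzzy
  approaches are deliberately out of scope).
* Only linear (affine) normalisation is provided — no nonlinear warps, no
  bias-field correction, no DICOM ingestion, no 4-D time series.
* The registration cost assumes a meaningful zero background (as produced
  by skull-stripping or a reconstruction mask); images with nonzero
  background pedestals should be masked first.
* Volumes are reported for the template grid's voxel size; acquisition
  with thick slices (e.g. 5 mm FLAIR) upsampled to a 1 mm template carries
  interpolation uncertainty that the volume numbers do not express.
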