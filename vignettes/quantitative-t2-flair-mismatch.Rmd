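---
title: "Quantitative T2-FLAIR mismatch and normalized ADC: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T2-FLAIR mismatch and normalized ADC: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mismatchmap)
```

## The problem

The T2-FLAIR mismatch sign — a T2-hyperintense tumor whose interior is
relatively FLAIR-hypointense except for a hyperintense peripheral rim — is a
highly specific but insensitive imaging marker of IDH-mutant, 1p/19q-intact
astrocytoma (IDHm-A) among non-enhancing diffuse gliomas. This package
implements a fully quantitative version of that assessment and its
comparison against diffusion MRI:

1. **Subtraction mapping.** T2-weighted and T2-weighted FLAIR volumes are
   z-score normalized to contralateral normal-appearing white matter (NAWM)
   so that NAWM signal is ~0 in both, then subtracted voxel-wise
   (normalized T2 minus normalized FLAIR). A fixed threshold of 0 splits the
   tumor VOI into the mismatch (T2FM, map > 0) and non-mismatch (T2FNM,
   map ≤ 0) subregions; `%T2FM-volume = 100 · V(T2FM) / V(tumor)`.
2. **Normalized ADC.** The ADC map is divided voxel-wise by the pooled mean
   ADC over three spherical NAWM reference VOIs; median nADC is extracted
   for the whole tumor and each subregion.
3. **Classification statistics.** Paired empirical ROC curves of nADC and
   %T2FM-volume for IDHm-A vs the other subtypes, compared with the DeLong
   test; threshold rules at 100% and ~95% specificity; multiple logistic
   regression; group contrasts with Holm–Šídák adjustment.
4. **Exploratory survival.** Kaplan–Meier, log-rank with Mantel–Haenszel
   hazard ratios at dichotomization cutoffs (%T2FM ≥ 2%, nADC ≥ 2.07,
   volume ≥ 60 mL), and univariate/multivariate Cox models.

Registration, skull-stripping and tumor segmentation are upstream of this
package: all volumes for one lesion must already share a grid, and the
pipeline refuses (rather than resamples) on a shape or affine mismatch.
Cyst/CSF exclusion is likewise the mask supplier's responsibility.

## Normalization choices

* NAWM statistics are pooled over the **union** of the three spheres'
  voxels, not averaged across per-sphere means — the simplest estimator
  consistent with "the mean ADC of three spherical VOIs".
* The z-score uses the **sample** SD (n−1). With hundreds to thousands of
  reference voxels the distinction is numerically irrelevant, but the choice
  is fixed and tested (NAWM mean 0 / SD 1 to 1e-10).
* The NAWM sphere radius is configurable with a default of 5 mm (a typical
  centrum-semiovale reference VOI; no canonical value exists).
* nADC is a pure ratio, so ADC may be supplied in mm²/s or 10⁻³ mm²/s; the
  declared unit is carried in the configuration for provenance only.
* Voxels exactly at 0 on the subtraction map are assigned to T2FNM, keeping
  the partition exhaustive; with continuous intensities this is a
  measure-zero event that only matters for synthetic exact-zero inputs.
* The median of an even-count region is the midpoint of the two central
  order statistics; the median of an empty subregion is `NA`, never 0.

## The lesion phantom

`phantom_spec()` / `generate_lesion_phantom()` build a spherical brain with
a spherical tumor and a **concentric core**: the simplest geometry with the
rim/core topology of the mismatch sign. For a target core volume fraction
`f`, the inner radius is `r_core = r_tumor · f^(1/3)`. A voxel belongs to a
sphere iff its center lies strictly within the radius; the same rule is used
for tumor, core and NAWM spheres, which makes voxel counts reproducible by
direct lattice enumeration (a 5 mm sphere on a 1 mm grid centered on a voxel
center contains exactly 485 voxels).

Intensity levels are free parameters (no published intensity statistics
exist for this normalization); the defaults
(T2 1.0/1.6/1.8, FLAIR 1.0/1.8/0.8 for background/rim/core) are chosen so
the subtraction-map signs are unambiguous at zero noise: on the rim the
FLAIR z-score exceeds the T2 z-score (map < 0) and on the core the order
reverses (map > 0). ADC defaults are 0.8/1.2/2.4 ×10⁻³ mm²/s
(NAWM/rim/core), i.e. noise-free subregion nADC of exactly 1.5 and 3.0 —
the elevated-core diffusivity expected from microcystic change.

Two deliberate numerical devices:

* **Deterministic texture.** A small sinusoidal field (amplitude 0.02,
  incommensurate periods) is added identically to T2 and FLAIR inside the
  brain. Without it a noise-free phantom would have zero NAWM variance and
  z-scoring would be undefined. Because the field — and hence the NAWM SD —
  is identical in both modalities, it cancels exactly in the subtraction
  map, so noise-free maps are positive **exactly** on core voxels. ADC
  carries no texture (its normalization uses only the NAWM mean).
* **Noise after structure.** Gaussian noise (independent per modality,
  default SD 0.05) is added after the levels and texture, inside the brain
  only, as in skull-stripped data. Rician noise and bias fields are
  non-goals.

NAWM spheres are mirrored across the mid-sagittal plane from the tumor
center and spread along the anterior–posterior axis at 2.5× their radius.
On the default 96³ · 1 mm grid the rasterized core fraction tracks the
target within well under 2 percentage points across the whole range; the
tests exercise fractions {0, 0.25, 0.42, 0.535, 1} end to end.

## The metric-level cohort simulator

`cohort_sim_spec()` emulates the cohort structure at the feature level so
the statistical battery can be exercised at realistic size and censoring.
Defaults (chosen once; they define the simulated study conditions):

* **Composition**: 27 mismatched IDHm-A, 38 non-mismatched IDHm-A, 18
  IDHm-O, 22 IDHwt lesions (105 total, 61.9% / 17.1% / 21.0% by subtype).
* **Whole-tumor nADC**: normal with means 2.6 / 2.1 / 1.8 / 1.6 and SD 0.3
  per group — the ordering mismatched > non-mismatched > IDHm-O > IDHwt.
* **Subregion contrast**: the T2FM−T2FNM nADC difference is drawn from a
  Gamma distribution with mean 0.58 and SD 0.2 and split symmetrically
  around the tumor value. A strictly positive draw encodes the within-lesion
  ordering as structural: in these simulations every mismatched lesion has
  a higher T2FM than T2FNM median, which is what the generator is meant to
  emulate, not a finding the pipeline discovers.
* **%T2FM-volume**: truncated normals — mismatched IDHm-A on [25, 100]
  (mean 45, SD 12), non-mismatched IDHm-A on [0, 25) (mean 8, SD 6), IDHm-O
  mean 8 SD 6 and IDHwt mean 4 SD 4 on [0, 100]. The key property is that
  most IDHm-A carry little mismatch volume while still having elevated
  nADC, which is exactly why nADC outperforms %T2FM-volume as a classifier
  in these cohorts.
* **Survival**: exponential event times per subtype (rates 7.3×10⁻⁵ /
  3×10⁻⁵ / 1.4×10⁻³ per day for IDHm-A / IDHm-O / IDHwt) under uniform
  administrative censoring on (0, 2600] days. The IDHm-A rate is tuned a
  priori so ~9% of IDHm-A records reach the endpoint; the ordering
  IDHwt ≪ IDHm-A < IDHm-O is preserved. A configurable fraction (default
  0.7) is flagged as the open-archive subset; the remainder is fully
  censored, and survival analysis is restricted to the flagged subset.
* **Clinical fields**: age ~ N(42, 12²) truncated to [18, 85]; tumor volume
  log-normal (median 40 mL); grades drawn with IDHm-A 44:20:1 (2:3:4),
  IDHm-O 17:1 (2:3), IDHwt grade 4.

What the simulator does **not** emulate: image-level noise propagation into
the metrics, inter-rater segmentation variability, correlated markers
beyond the shared tumor value, non-proportional hazards, or the real
cohort's exact marker distributions. Passing tests on these simulations
therefore validate the pipeline's statistical machinery and orderings, not
the real-data AUC, sensitivity or hazard-ratio values, which require the
original images.

## Statistical implementation notes

* **ROC**: operating points are the strict rules "positive if score > t"
  over distinct observed scores plus the extremes; tied scores form one
  step; AUC by trapezoid. `auc_concordance()` is an independent
  rank-based Mann–Whitney implementation; the two agree to 1e-12 on every
  dataset and this equivalence is asserted in the tests.
* **Threshold rules** report the operating point with maximal sensitivity
  among those with specificity ≥ target, as a strict ">" cutoff; at a 100%
  target this is the maximum negative-class score. A "~95%" target is
  interpreted as "specificity ≥ 95%" rather than "nearest attainable
  operating point"; with few negatives the achieved specificity is
  accordingly a coarse multiple of 1/n.
* **DeLong**: placement values per subject; covariances with m−1 / n−1
  denominators; two-sided normal p. Zero variance with equal AUCs returns
  p = 1 with a `degenerate` flag; zero variance with unequal AUCs is an
  error.
* **Group contrasts**: the between-subject comparison across molecular
  groups is implemented as independent pairwise t-tests (pooled variance by
  default, Welch by flag) with Holm–Šídák adjustment
  (`1 − (1 − p)^(m−i+1)` with a running maximum); the within-lesion
  subregion contrast is a paired t-test. A repeated-measures formulation
  across molecular types is not meaningful since the groups are different
  patients.
* **Log-rank**: hand-summed O−E with hypergeometric variance over distinct
  event times, k groups; Mantel–Haenszel HR = (O₁/E₁)/(O₂/E₂) with
  log-normal CI via se = √(1/E₁ + 1/E₂). With zero events in one arm the
  HR degenerates to 0/∞ and the CI is reported `NA`. `survival::survdiff`
  serves as an independent oracle in the tests.
* **Cox**: `survival::coxph` (Newton–Raphson, Efron ties, tolerance 1e-8)
  behind `cox_fit()`, with flags for under-identification (fewer events
  than covariates) and monotone-likelihood divergence. For a binary
  covariate without ties the score test equals the log-rank chi-square
  (checked to 1e-6).
* **Logistic**: `stats::glm` IRLS (epsilon 1e-8, maxit 100) behind
  `fit_logistic()`; separation is detected from pinned fitted probabilities
  and flagged rather than reported as converged coefficients.

## Problem sizes in the test suite

Unit tests use 48³ phantoms; the recovery property runs eleven core
fractions on a 64³ grid and the end-to-end acceptance checks use the
default 96³ grid. Monte-Carlo checks use 2000 replicates for DeLong null
calibration at the 65/40 class split, 200 replicates each for the Cox
log-HR recovery (n = 300) and the nADC-preference rate (n = 105 cohorts),
and 200 replicates (n = 200) for Mantel–Haenszel consistency. These sizes
give Monte-Carlo standard errors well inside the asserted bands while
keeping the whole suite in the low minutes.

## Known limitations

* Spherical geometry and three-level intensities are a deliberately minimal
  stand-in for real anatomy; no template brains, multifocality, contrast
  enhancement, Rician noise or bias fields.
* The pipeline never resamples; misregistered inputs are rejected, not
  corrected.
* Simulated cohorts demonstrate orderings and calibration, not real-data
  effect sizes.
* The extent-of-resection covariate has no canonical coding; it is taken as
  supplied in the manifest.
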