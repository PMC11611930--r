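# mismatchmap

Quantitative T2-FLAIR mismatch and normalized-ADC analysis of non-enhancing
diffuse gliomas, as an R package plus a reproducible analysis workflow.

The T2-FLAIR mismatch sign — a T2-hyperintense tumor with a relatively
FLAIR-hypointense core and hyperintense peripheral rim — is a near-100%
specific but insensitive marker of IDH-mutant 1p/19q-intact astrocytoma
(IDHm-A). `mismatchmap` quantifies it and compares it against diffusion
MRI:

* **Maps.** T2 and FLAIR are z-scored to three spherical NAWM reference
  VOIs in the contralateral centrum semiovale and subtracted voxel-wise
  (`zscore_normalize()`, `build_subtraction_map()`); a fixed threshold of 0
  splits the tumor VOI into mismatch (T2FM, map > 0) and non-mismatch
  (T2FNM) subregions (`split_subregions()`). ADC is divided by the pooled
  NAWM mean to give nADC (`build_nadc_map()`).
* **Features.** Per lesion: tumor/T2FM/T2FNM volumes (mL),
  %T2FM-volume = 100·V(T2FM)/V(tumor), median nADC of tumor and subregions,
  and the ≥25% "mismatched" flag (`compute_lesion_metrics()`, `run_lesion()`).
* **Statistics.** Paired empirical ROC of nADC vs %T2FM-volume with the
  DeLong test (`empirical_roc()`, `delong_test()`), threshold rules at
  100%/95% specificity (`select_threshold_at_specificity()`), logistic
  models (`fit_logistic()`), Holm–Šídák-adjusted group contrasts
  (`group_comparisons()`), and exploratory survival analysis: Kaplan–Meier,
  log-rank with Mantel–Haenszel HR, Cox regression (`km_fit()`,
  `logrank_test()`, `cox_fit()`); all orchestrated by
  `run_cohort_analysis()`.
* **Synthetic data.** A lesion phantom with known core fraction and a
  metric-level cohort simulator (`generate_lesion_phantom()`,
  `simulate_metric_cohort()`) make every stage testable without patient
  data.

Inputs are co-registered, skull-stripped NIfTI volumes on one grid;
registration, skull-stripping and segmentation are out of scope and grid
mismatches are errors, never resampled away.

## Worked example

```r
library(mismatchmap)

# a "mismatched" astrocytoma-like phantom: 53.5% core, elevated core ADC
ph <- generate_lesion_phantom(phantom_spec(core_fraction = 0.535, noise_sd = 0))
m  <- run_lesion(ph$t2, ph$flair, ph$adc, ph$tumor_mask, ph$nawm)
m[, c("tumor_ml", "pct_t2fm", "nadc_tumor", "nadc_t2fm", "nadc_t2fnm")]
#>   tumor_ml pct_t2fm nadc_tumor nadc_t2fm nadc_t2fnm
#> 1   14.328 52.81965          3         3        1.5
```

The recovered %T2FM-volume (52.8%) matches the constructed core fraction to
within sphere rasterization, and the subregion nADC medians equal the
built-in ADC ratios exactly (core 2.4/0.8 = 3.0, rim 1.2/0.8 = 1.5).

The cohort-level battery on a simulated 105-lesion series
(`analysis/02_simulate_cohort.R` then `analysis/03_classification.R`):

```
== paired ROC tasks ==
IDHm-A vs IDHm-O/IDHwt   AUC nADC 0.924 vs %T2FM 0.822   DeLong p = 0.01376
IDHm-A vs IDHm-O         AUC nADC 0.884 vs %T2FM 0.784   DeLong p = 0.06417
IDHm-A vs IDHwt          AUC nADC 0.957 vs %T2FM 0.854   DeLong p = 0.02926
```

Whole-tumor nADC beats %T2FM-volume here because most simulated IDHm-A
carry little mismatch volume yet still have elevated diffusivity — the
property the simulator is built to emulate.

## Analysis workflow

Numbered drivers under `analysis/` write tables to `results/` (volumes go
to `scratch/`):

1. `01_phantom_demo.R` — four representative phantoms through the
   per-lesion pipeline.
2. `02_simulate_cohort.R` — screening cascade (645 → 104) and the simulated
   105-lesion cohort CSV.
3. `03_classification.R` — group comparisons, paired ROC + DeLong,
   threshold table, logistic models.
4. `04_survival.R` — KM, dichotomized log-rank + MH-HR, Cox models on the
   heavily censored survival subset.

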