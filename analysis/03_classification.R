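#!/usr/bin/env Rscript
# Classification battery on the simulated cohort from 02_simulate_cohort.R:
# group comparisons with Holm-Sidak-adjusted pairwise contrasts, the three
# paired ROC tasks (IDHm-A vs IDHm-O+IDHwt / vs IDHm-O / vs IDHwt) with the
# DeLong paired-AUC test, specificity-constrained threshold rules at 100%
# and 95%, and the three logistic models.

suppressPackageStartupMessages(library(mismatchmap))
if (!file.exists("results/cohort.csv"))
  stop("run analysis/02_simulate_cohort.R first")
d <- read.csv("results/cohort.csv")
d$group <- factor(d$group, levels = c("IDHm-A>=25%", "IDHm-A<25%",
                                      "IDHm-O", "IDHwt"))

rep <- run_cohort_analysis(d)

gc <- rep$group_comparisons
write.csv(gc, "results/group_comparisons.csv", row.names = FALSE)
cat("== group comparisons (nADC) ==\n")
print(gc[, c("contrast", "mean_diff", "p_raw", "p_adj")], digits = 3)

cat("\n== paired ROC tasks ==\n")
for (tk in rep$roc_tasks) {
  cat(sprintf("%-24s AUC nADC %.3f vs %%T2FM %.3f   DeLong p = %.4g\n",
              tk$task, tk$auc_nadc, tk$auc_pct_t2fm, tk$delong$p_two_sided))
}

cat("\n== logistic models (in-sample AUC) ==\n")
for (nm in names(rep$logistic)) {
  a <- vapply(rep$logistic[[nm]], `[[`, numeric(1), "auc")
  cat(sprintf("%-24s nADC %.3f | +%%T2FM %.3f | +age %.3f\n",
              nm, a["nadc"], a["nadc_pct"], a["nadc_pct_age"]))
}

write_cohort_report(rep, "results/classification_report.json")
cat("\nreport written to results/classification_report.json (+ .txt threshold table)\n")
cat("On these simulated cohorts whole-tumor nADC separates IDHm-A from the\n")
cat("other subtypes better than %T2FM-volume, because a large fraction of\n")
cat("IDHm-A carry little mismatch volume yet still have elevated diffusivity.\n")
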