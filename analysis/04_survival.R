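#!/usr/bin/env Rscript
# Exploratory survival analysis on the simulated cohort (open-archive subset
# only; the institutional subset is fully censored by construction):
# Kaplan-Meier within IDHm-A, dichotomized log-rank tests with
# Mantel-Haenszel hazard ratios at the default cutoffs (%T2FM >= 2%,
# nADC >= 2.07, volume >= 60 mL), the three-subtype log-rank, and
# univariate / multivariate Cox models.

suppressPackageStartupMessages(library(mismatchmap))
if (!file.exists("results/cohort.csv"))
  stop("run analysis/02_simulate_cohort.R first")
d <- read.csv("results/cohort.csv")
d$group <- factor(d$group, levels = c("IDHm-A>=25%", "IDHm-A<25%",
                                      "IDHm-O", "IDHwt"))

rep <- run_cohort_analysis(d)
sv <- rep$survival
cat("survival subset:", sv$n, "lesions,", sv$n_events, "events\n")
cat("IDHm-A KM median:",
    if (is.na(sv$idhm_a_km$median)) "not reached (heavy censoring)"
    else paste(sv$idhm_a_km$median, "days"), "\n\n")

cat("== dichotomized log-rank within IDHm-A ==\n")
for (nm in names(sv$dichotomized)) {
  x <- sv$dichotomized[[nm]]
  if (is.null(x)) { cat(nm, ": skipped (degenerate split)\n"); next }
  cat(sprintf("%-10s chi2 %.2f p %.3f  MH-HR %.2f (95%% CI %.2f-%.2f)\n",
              nm, x$logrank$chi2, x$logrank$p, x$logrank$mantel_haenszel_hr,
              x$logrank$hr_ci_95[1], x$logrank$hr_ci_95[2]))
}

cat("\n== subtype log-rank ==\n")
print(sv$subtype_logrank)

cat("\n== Cox (IDHm-A, continuous covariates) ==\n")
for (nm in names(sv$cox_univariate)) {
  tb <- sv$cox_univariate[[nm]]$table
  cat(sprintf("univariate %-10s HR %.3f (%.3f-%.3f) p %.3f\n",
              nm, tb$hr, tb$ci_lo, tb$ci_hi, tb$p))
}
if (!is.null(sv$cox_multivariate)) {
  cat("multivariate (adjusted for age, grade):\n")
  print(sv$cox_multivariate$table, digits = 3)
}

km <- sv$idhm_a_km
write.csv(data.frame(time = km$time, surv = km$surv, n_risk = km$n_risk,
                     n_event = km$n_event),
          "results/km_idhm_a.csv", row.names = FALSE)
jsonlite::write_json(
  list(n = sv$n, n_events = sv$n_events,
       km_median_idhm_a = km$median,
       dichotomized = lapply(sv$dichotomized, function(x) if (is.null(x)) NULL
         else list(chi2 = x$logrank$chi2, p = x$logrank$p,
                   hr = x$logrank$mantel_haenszel_hr,
                   ci = x$logrank$hr_ci_95,
                   median_high = x$median_high, median_low = x$median_low)),
       subtype_logrank = list(chi2 = sv$subtype_logrank$chi2,
                              p = sv$subtype_logrank$p)),
  "results/survival_report.json", auto_unbox = TRUE, digits = NA,
  null = "null")
cat("\nKM table -> results/km_idhm_a.csv; report -> results/survival_report.json\n")
cat("With ~9% of IDHm-A reaching the endpoint the dichotomized hazard ratios\n")
cat("carry very wide confidence intervals, as expected at these event counts.\n")
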