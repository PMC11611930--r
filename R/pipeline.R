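#' Pipeline configuration
#'
#' Collects the analysis constants in one place; all of them are defaults
#' here, never hard-coded in the computation functions. ADC units only affect
#' interpretation: nADC is a ratio and is unchanged between mm^2/s and
#' 1e-3 mm^2/s.
#'
#' @param adc_units units of the supplied ADC maps.
#' @param nawm_radius_mm NAWM reference sphere radius.
#' @param mismatch_threshold %T2FM-volume cutoff defining "mismatched"
#'   lesions; default 25.
#' @param specificity_targets specificity targets (percent) for the
#'   threshold table; default c(100, 95).
#' @param surv_cutoffs dichotomization cutoffs for exploratory survival:
#'   %T2FM-volume (percent), nADC, tumor volume (mL).
#' @param seed default seed for any randomized step.
#' @export
mismatch_config <- function(adc_units = c("1e-3 mm^2/s", "mm^2/s"),
                            nawm_radius_mm = 5,
                            mismatch_threshold = 25,
                            specificity_targets = c(100, 95),
                            surv_cutoffs = c(pct_t2fm = 2, nadc = 2.07,
                                             volume_ml = 60),
                            seed = 1L) {
  adc_units <- match.arg(adc_units)
  if (mismatch_threshold < 0 || mismatch_threshold > 100)
    stop("`mismatch_threshold` must be a percentage")
  if (any(specificity_targets <= 0 | specificity_targets > 100))
    stop("`specificity_targets` must lie in (0, 100]")
  structure(list(adc_units = adc_units, nawm_radius_mm = nawm_radius_mm,
                 mismatch_threshold = mismatch_threshold,
                 specificity_targets = specificity_targets,
                 surv_cutoffs = surv_cutoffs, seed = as.integer(seed)),
            class = "mismatch_config")
}

#' Per-lesion pipeline: maps, subregions, metrics
#'
#' Chains NAWM rasterization, z-score normalization of T2 and FLAIR,
#' voxel-wise subtraction, ADC normalization, subregion splitting at
#' threshold 0 and feature extraction for one lesion. Deterministic for
#' fixed inputs.
#'
#' @param t2,flair,adc `image_volume`s on one grid.
#' @param tumor_mask tumor VOI `mask_volume` (cysts/CSF already excluded
#'   upstream).
#' @param nawm a [nawm_spec()] or a NAWM `mask_volume`.
#' @param config a [mismatch_config()].
#' @param out_dir if non-NULL, the subtraction map, nADC map, subregion
#'   masks (NIfTI) and metrics JSON are written there.
#' @return `lesion_metrics` one-row data.frame; the maps and masks are
#'   attached as attribute "volumes".
#' @export
run_lesion <- function(t2, flair, adc, tumor_mask, nawm,
                       config = mismatch_config(), out_dir = NULL) {
  assert_same_grid(t2, flair, "T2 and FLAIR")
  assert_same_grid(t2, adc, "T2 and ADC")
  assert_same_grid(t2, tumor_mask, "T2 and tumor mask")
  nawm_mask <- if (inherits(nawm, "nawm_spec"))
    rasterize_nawm_spheres(nawm, t2) else nawm
  assert_same_grid(t2, nawm_mask, "T2 and NAWM mask")
  t2z <- zscore_normalize(t2, nawm_mask)
  flairz <- zscore_normalize(flair, nawm_mask)
  sub_map <- build_subtraction_map(t2z, flairz)
  nadc <- build_nadc_map(adc, nawm_mask)
  sr <- split_subregions(sub_map, tumor_mask)
  metrics <- compute_lesion_metrics(sr$t2fm, sr$t2fnm, nadc,
                                    mismatch_threshold = config$mismatch_threshold)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
    write_image_volume(sub_map, file.path(out_dir, "subtraction.nii.gz"))
    write_image_volume(nadc, file.path(out_dir, "nadc.nii.gz"))
    write_image_volume(sr$t2fm, file.path(out_dir, "t2fm_mask.nii.gz"))
    write_image_volume(sr$t2fnm, file.path(out_dir, "t2fnm_mask.nii.gz"))
    jsonlite::write_json(as.list(metrics), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(metrics, "volumes") <- list(subtraction = sub_map, nadc = nadc,
                                   t2fm = sr$t2fm, t2fnm = sr$t2fnm)
  metrics
}

#' Sequential inclusion filtering with an exclusion tally
#'
#' Applies the four eligibility criteria in order — non-enhancing adult-type
#' diffuse glioma, supratentorial location, treatment-naive (biopsy only),
#' molecular status available — each as a logical pass/fail column, counting
#' exclusions per criterion (each subject excluded once, at the first
#' criterion it fails).
#'
#' @param screening `data.frame` with logical columns `non_enhancing_diffuse`,
#'   `supratentorial`, `treatment_naive`, `molecular_available`.
#' @return list: `table` (rows passing all criteria), `tally` (named
#'   exclusion counts), `n_screened`, `n_included`.
#' @export
apply_inclusion_filters <- function(screening) {
  criteria <- c("non_enhancing_diffuse", "supratentorial",
                "treatment_naive", "molecular_available")
  missing_cols <- setdiff(criteria, names(screening))
  if (length(missing_cols))
    stop("screening table lacks criterion columns: ",
         paste(missing_cols, collapse = ", "))
  tally <- stats::setNames(integer(length(criteria)), criteria)
  keep <- screening
  for (cr in criteria) {
    fails <- !as.logical(keep[[cr]])
    tally[cr] <- sum(fails)
    keep <- keep[!fails, , drop = FALSE]
  }
  list(table = keep, tally = tally,
       n_screened = nrow(screening), n_included = nrow(keep))
}

#' Diagnosis percentages, cohort-table convention
#'
#' 100 * count / total rounded to one decimal.
#'
#' @param counts named integer vector of per-subtype lesion counts.
#' @export
subtype_percentages <- function(counts) {
  round(100 * counts / sum(counts), 1)
}

roc_task <- function(cohort, positive, negative, label, targets) {
  sel <- cohort$subtype %in% c(positive, negative)
  d <- cohort[sel, , drop = FALSE]
  y <- d$subtype == positive
  if (sum(y) < 1 || sum(!y) < 1) return(NULL)
  roc_nadc <- empirical_roc(d$nadc_tumor, y)
  roc_pct <- empirical_roc(d$pct_t2fm, y)
  dl <- delong_test(d$nadc_tumor, d$pct_t2fm, y)
  thr <- lapply(targets, function(tg) {
    rbind(
      data.frame(marker = "nADC", target_specificity = tg,
                 t(unlist(select_threshold_at_specificity(roc_nadc, tg)[
                   c("cutoff", "achieved_sensitivity", "achieved_specificity")]))),
      data.frame(marker = "%T2FM-volume", target_specificity = tg,
                 t(unlist(select_threshold_at_specificity(roc_pct, tg)[
                   c("cutoff", "achieved_sensitivity", "achieved_specificity")])))
    )
  })
  thr <- do.call(rbind, thr)
  rownames(thr) <- NULL
  list(task = label, n_pos = sum(y), n_neg = sum(!y),
       auc_nadc = roc_nadc$auc, auc_pct_t2fm = roc_pct$auc,
       delong = dl, thresholds = thr)
}

#' Full cohort analysis battery
#'
#' Given a cohort table of per-lesion metrics and clinical fields, produces:
#' group comparisons (subregion paired t, four-group pairwise t with
#' Holm-Sidak, grade contrast); the three paired ROC classification tasks
#' (IDHm-A vs IDHm-O+IDHwt, vs IDHm-O, vs IDHwt) with the DeLong test and a
#' threshold table at the configured specificity targets; logistic models
#' (nADC; nADC + %T2FM; nADC + %T2FM + age) per task; and the exploratory
#' survival section (KM + log-rank with Mantel-Haenszel HR at the configured
#' dichotomization cutoffs within IDHm-A, the three-subtype log-rank, and
#' univariate + multivariate Cox), restricted to the open-archive (`tcia`)
#' subset when a `cohort` column is present.
#'
#' @param cohort cohort `data.frame` (see [simulate_metric_cohort()] for the
#'   column contract).
#' @param config a [mismatch_config()].
#' @return nested list report (class `cohort_report`).
#' @export
run_cohort_analysis <- function(cohort, config = mismatch_config()) {
  required <- c("lesion_id", "subtype", "nadc_tumor", "pct_t2fm")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cohort$lesion_id))
    stop("lesion ids must be unique")
  if (length(unique(cohort$subtype)) < 2)
    stop("need at least 2 subtypes for classification")
  if (!("group" %in% names(cohort))) {
    cohort$group <- ifelse(
      cohort$subtype == "IDHm-A",
      ifelse(cohort$pct_t2fm >= config$mismatch_threshold,
             "IDHm-A>=25%", "IDHm-A<25%"),
      cohort$subtype)
    cohort$group <- factor(cohort$group, levels = group_levels)
  }
  report <- list(config = unclass(config),
                 n_lesions = nrow(cohort),
                 subtype_counts = table(cohort$subtype),
                 subtype_pct = subtype_percentages(table(cohort$subtype)))

  report$group_comparisons <-
    if (all(c("grade", "nadc_t2fm", "nadc_t2fnm") %in% names(cohort)))
      group_comparisons(cohort) else NULL

  tasks <- list(
    c("IDHm-A vs IDHm-O/IDHwt", "IDHm-O", "IDHwt"),
    c("IDHm-A vs IDHm-O", "IDHm-O"),
    c("IDHm-A vs IDHwt", "IDHwt")
  )
  report$roc_tasks <- list()
  report$logistic <- list()
  for (tk in tasks) {
    res <- roc_task(cohort, "IDHm-A", tk[-1], tk[1],
                    config$specificity_targets)
    if (is.null(res)) {
      warning("classification task skipped (degenerate classes): ", tk[1])
      next
    }
    report$roc_tasks[[tk[1]]] <- res
    sel <- cohort$subtype %in% c("IDHm-A", tk[-1])
    d <- cohort[sel, , drop = FALSE]
    y <- d$subtype == "IDHm-A"
    models <- list(nadc = d[, "nadc_tumor", drop = FALSE],
                   nadc_pct = d[, c("nadc_tumor", "pct_t2fm")])
    if ("age" %in% names(d))
      models$nadc_pct_age <- d[, c("nadc_tumor", "pct_t2fm", "age")]
    report$logistic[[tk[1]]] <- lapply(models, function(ft) {
      f <- fit_logistic(ft, y)
      list(coefficients = f$coefficients, auc = f$auc,
           separation = f$separation, converged = f$converged)
    })
  }

  surv_ok <- all(c("os_days", "event") %in% names(cohort)) &&
    any(cohort$event == 1)
  report$survival <- if (surv_ok) {
    sv <- cohort
    if ("cohort" %in% names(sv)) sv <- sv[sv$cohort == "tcia", , drop = FALSE]
    surv_section(sv, config)
  } else NULL
  class(report) <- "cohort_report"
  report
}

surv_section <- function(sv, config) {
  out <- list(n = nrow(sv), n_events = sum(sv$event))
  a <- sv[sv$subtype == "IDHm-A", , drop = FALSE]
  cuts <- config$surv_cutoffs
  dich <- list(
    pct_t2fm = a$pct_t2fm >= cuts[["pct_t2fm"]],
    nadc = a$nadc_tumor >= cuts[["nadc"]],
    volume_ml = if ("volume_ml" %in% names(a))
      a$volume_ml >= cuts[["volume_ml"]] else NULL
  )
  out$idhm_a_km <- if (nrow(a) > 0) km_fit(a$os_days, a$event) else NULL
  out$dichotomized <- lapply(dich, function(g) {
    if (is.null(g) || length(unique(g)) < 2 || sum(a$event) < 1) return(NULL)
    lr <- logrank_test(a$os_days, a$event, factor(g, levels = c(TRUE, FALSE),
                                                  labels = c("high", "low")))
    km_hi <- km_fit(a$os_days[g], a$event[g])
    km_lo <- km_fit(a$os_days[!g], a$event[!g])
    list(logrank = lr, median_high = km_hi$median, median_low = km_lo$median)
  })
  out$subtype_logrank <- if (length(unique(sv$subtype)) >= 2 &&
                             sum(sv$event) >= 1)
    logrank_test(sv$os_days, sv$event, sv$subtype) else NULL
  covs <- intersect(c("pct_t2fm", "nadc_tumor", "volume_ml"), names(a))
  adj <- intersect(c("age", "grade"), names(a))
  if (nrow(a) >= 3 && sum(a$event) >= 1) {
    out$cox_univariate <- lapply(stats::setNames(covs, covs), function(cv) {
      cox_fit(a$os_days, a$event, a[, cv, drop = FALSE])
    })
    if (sum(a$event) >= length(c(covs, adj)))
      out$cox_multivariate <- tryCatch(
        cox_fit(a$os_days, a$event, a[, c(covs, adj), drop = FALSE]),
        error = function(e) NULL)
  }
  out
}

#' Write a cohort report as JSON plus a readable threshold table
#'
#' @param report a `cohort_report`.
#' @param path JSON output path; a sibling `.txt` threshold table is written
#'   alongside.
#' @export
write_cohort_report <- function(report, path) {
  jsonlite::write_json(serialize_report(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  txt <- sub("\\.json$", ".txt", path)
  lines <- c("Threshold summary (per classification task)", "")
  for (tk in report$roc_tasks) {
    lines <- c(lines, sprintf("== %s (AUC nADC %.3f vs %%T2FM %.3f, DeLong p %.4g)",
                              tk$task, tk$auc_nadc, tk$auc_pct_t2fm,
                              tk$delong$p_two_sided))
    tt <- tk$thresholds
    lines <- c(lines, sprintf("  %-14s > %-8.4g sens %5.1f%%  spec %5.1f%% (target %g%%)",
                              tt$marker, tt$cutoff, tt$achieved_sensitivity,
                              tt$achieved_specificity, tt$target_specificity))
    lines <- c(lines, "")
  }
  writeLines(lines, txt)
  invisible(path)
}

serialize_report <- function(x) {
  if (inherits(x, "km_fit") || inherits(x, "logrank_result") ||
      inherits(x, "delong_result") || inherits(x, "cox_result"))
    x <- unclass(x)
  if (is.list(x)) return(lapply(x, serialize_report))
  if (is.table(x)) return(as.list(x))
  x
}
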