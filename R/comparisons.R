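#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sort the m raw p-values ascending; the i-th smallest is adjusted to
#' 1 - (1 - p_(i))^(m - i + 1); a running maximum enforces step-down
#' monotonicity; results are returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
holm_sidak_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

pair_t_row <- function(x, y, paired = FALSE, var.equal = TRUE, label) {
  n_ok <- if (paired) sum(is.finite(x) & is.finite(y)) else
    min(sum(is.finite(x)), sum(is.finite(y)))
  if (n_ok < 2L) {
    return(data.frame(contrast = label, mean_diff = NA_real_, t = NA_real_,
                      df = NA_real_, p_raw = NA_real_, degenerate = NA,
                      skipped = TRUE))
  }
  if (paired) {
    d <- x - y
    if (stats::sd(d) == 0) {
      return(data.frame(contrast = label, mean_diff = mean(d), t = NA_real_,
                        df = NA_real_, p_raw = NA_real_, degenerate = TRUE,
                        skipped = FALSE))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      deg_p <- if (mean(x) == mean(y)) 1 else NA_real_
      return(data.frame(contrast = label, mean_diff = mean(x) - mean(y),
                        t = if (mean(x) == mean(y)) 0 else NA_real_,
                        df = NA_real_, p_raw = deg_p, degenerate = TRUE,
                        skipped = FALSE))
    }
    tt <- stats::t.test(x, y, var.equal = var.equal)
  }
  data.frame(contrast = label, mean_diff = mean(x) - mean(y),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_raw = tt$p.value, degenerate = FALSE, skipped = FALSE)
}

#' Group comparison battery for a lesion cohort
#'
#' Runs the cohort's standard contrasts on whole-tumor and subregion nADC:
#' \itemize{
#'   \item a paired t-test of T2FM vs T2FNM subregion nADC within mismatched
#'     (>= 25% T2FM-volume) IDH-mutant astrocytomas;
#'   \item all pairwise two-sample t-tests of whole-tumor nADC across the
#'     four groups (mismatched IDHm-A, non-mismatched IDHm-A, IDHm-O,
#'     IDHwt), Holm-Sidak adjusted over the six-contrast family;
#'   \item an unpaired t-test of whole-tumor nADC between grade 2 and
#'     grade 3 IDHm-A.
#' }
#' Contrasts whose groups have fewer than 2 usable observations are skipped
#' with a warning.
#'
#' @param cohort cohort `data.frame` (columns group, subtype, grade,
#'   nadc_tumor, nadc_t2fm, nadc_t2fnm).
#' @param var_equal use the pooled-variance t-test (default TRUE); FALSE
#'   gives the Welch variant.
#' @return `data.frame` report: family, contrast, mean_diff, t, df, p_raw,
#'   p_adj, degenerate, skipped.
#' @export
group_comparisons <- function(cohort, var_equal = TRUE) {
  stopifnot(all(c("group", "subtype", "grade", "nadc_tumor") %in% names(cohort)))
  rows <- list()

  mm <- cohort[cohort$group == "IDHm-A>=25%", , drop = FALSE]
  if (all(c("nadc_t2fm", "nadc_t2fnm") %in% names(cohort))) {
    r <- pair_t_row(mm$nadc_t2fm, mm$nadc_t2fnm, paired = TRUE,
                    label = "T2FM vs T2FNM nADC (mismatched IDHm-A, paired)")
    r$family <- "paired_subregion"
    r$p_adj <- r$p_raw
    rows[[length(rows) + 1L]] <- r
  }

  lv <- levels(factor(cohort$group, levels = group_levels))
  pair_idx <- utils::combn(lv, 2, simplify = FALSE)
  fam <- lapply(pair_idx, function(pr) {
    x <- cohort$nadc_tumor[cohort$group == pr[1]]
    y <- cohort$nadc_tumor[cohort$group == pr[2]]
    pair_t_row(x, y, var.equal = var_equal,
               label = paste(pr[1], "vs", pr[2]))
  })
  fam <- do.call(rbind, fam)
  fam$family <- "group_nadc"
  fam$p_adj <- NA_real_
  usable <- !fam$skipped & !is.na(fam$p_raw)
  fam$p_adj[usable] <- holm_sidak_adjust(fam$p_raw[usable])
  rows[[length(rows) + 1L]] <- fam

  a <- cohort[cohort$subtype == "IDHm-A", , drop = FALSE]
  r <- pair_t_row(a$nadc_tumor[a$grade == 2], a$nadc_tumor[a$grade == 3],
                  var.equal = var_equal,
                  label = "grade 2 vs grade 3 IDHm-A")
  r$family <- "grade"
  r$p_adj <- r$p_raw
  rows[[length(rows) + 1L]] <- r

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$skipped))
    warning("contrasts skipped (fewer than 2 usable observations): ",
            paste(out$contrast[out$skipped], collapse = "; "))
  out[c("family", "contrast", "mean_diff", "t", "df", "p_raw", "p_adj",
        "degenerate", "skipped")]
}
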