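#' DeLong test for two paired (correlated) AUCs
#'
#' Both markers score the same subjects. For each marker the per-subject
#' placement values (structural components) are computed: for a positive
#' subject, the fraction of negatives it outranks (ties 1/2); for a negative
#' subject, the fraction of positives ranking above it. The 2x2 covariance
#' matrix of the AUCs combines the sample covariances of the placement
#' values (denominators m-1 and n-1) scaled by 1/m and 1/n, and
#' z = (AUC_a - AUC_b) / sqrt(var_diff) is referred to the standard normal.
#'
#' @param scores_a,scores_b marker values for the same subjects.
#' @param labels positive-class indicator.
#' @return list (class `delong_result`): auc_a, auc_b, var_diff, z_statistic,
#'   p_two_sided, degenerate flag.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length")
  if (!any(labels) || all(labels)) stop("both classes must be present")

  placement <- function(s) {
    pos <- s[labels]; neg <- s[!labels]
    m <- length(pos); n <- length(neg)
    v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                  numeric(1))
    v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placement(scores_a)
  pb <- placement(scores_b)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))   # (m-1) denominator
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  degenerate <- var_diff <= .Machine$double.eps
  if (degenerate && abs(d) > 1e-12)
    stop("zero variance of the AUC difference with unequal AUCs")
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = max(var_diff, 0),
                 z_statistic = z, p_two_sided = p, degenerate = degenerate),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: AUC_a %.3f vs AUC_b %.3f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$z_statistic, x$p_two_sided,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
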