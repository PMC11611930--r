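#' Empirical ROC curve
#'
#' Operating points are the rules "call positive if score > t" for t ranging
#' over the distinct observed scores plus the two trivial extremes, so tied
#' scores collapse into a single step. AUC is computed by the trapezoidal
#' rule over (1 - specificity, sensitivity).
#'
#' @param scores numeric marker values, finite.
#' @param labels logical (or 0/1) positive-class indicator.
#' @param direction `">"` if larger scores indicate the positive class (the
#'   default), `"<"` to flip the marker sign internally.
#' @return object of class `roc_curve`: thresholds, sensitivity, specificity,
#'   auc, direction.
#' @export
empirical_roc <- function(scores, labels, direction = c(">", "<")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!any(labels) || all(labels))
    stop("both classes must be present to build a ROC curve")
  s <- if (direction == "<") -scores else scores
  pos <- s[labels]
  neg <- s[!labels]
  thr <- c(-Inf, sort(unique(s)))
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  # trapezoid over the (FPR, TPR) polyline, ordered by increasing FPR
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  structure(list(thresholds = if (direction == "<") -thr else thr,
                 sensitivity = sens, specificity = spec,
                 auc = auc, direction = direction),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f over %d operating points\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Mann-Whitney concordance AUC
#'
#' Independent of the ROC construction: the mean over all positive-negative
#' pairs of 1 (positive scored higher), 1/2 (tie), 0 (lower). Equals the
#' trapezoidal AUC of [empirical_roc()] on every dataset.
#'
#' @inheritParams empirical_roc
#' @return scalar AUC.
#' @export
auc_concordance <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pos <- scores[labels]
  neg <- scores[!labels]
  # rank-based evaluation, O(n log n): AUC = (R_pos - m(m+1)/2) / (m n)
  r <- rank(c(pos, neg))
  m <- length(pos); n <- length(neg)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Pick a threshold at a target specificity
#'
#' Among operating points achieving at least the target specificity, returns
#' the one with maximal sensitivity (ties broken toward higher specificity,
#' then the lower cutoff). The rule is reported as strict: call positive when
#' score > cutoff. At a 100% target the cutoff is the maximum negative-class
#' score.
#'
#' @param roc a `roc_curve` from [empirical_roc()].
#' @param target_specificity in percent, (0, 100].
#' @return list (class `threshold_rule`): cutoff, direction,
#'   achieved_sensitivity, achieved_specificity, target_specificity
#'   (sens/spec in percent).
#' @export
select_threshold_at_specificity <- function(roc, target_specificity) {
  stopifnot(inherits(roc, "roc_curve"))
  if (target_specificity <= 0 || target_specificity > 100)
    stop("`target_specificity` must lie in (0, 100]")
  ok <- roc$specificity * 100 >= target_specificity
  if (!any(ok)) stop("no operating point attains the target specificity")
  cand <- which(ok)
  best <- cand[order(-roc$sensitivity[cand], -roc$specificity[cand],
                     roc$thresholds[cand])][1]
  structure(list(
    cutoff = roc$thresholds[best],
    direction = roc$direction,
    achieved_sensitivity = 100 * roc$sensitivity[best],
    achieved_specificity = 100 * roc$specificity[best],
    target_specificity = target_specificity
  ), class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("rule: score %s %g  (sens %.1f%%, spec %.1f%% >= target %.4g%%)\n",
              x$direction, x$cutoff, x$achieved_sensitivity,
              x$achieved_specificity, x$target_specificity))
  invisible(x)
}
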