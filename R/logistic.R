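#' Multiple logistic regression for lesion classification
#'
#' Maximum-likelihood fit of a binomial GLM (iteratively reweighted least
#' squares, convergence tolerance 1e-8, at most 100 iterations) of the
#' positive-class indicator on the supplied features, reporting the
#' in-sample AUC of the fitted probabilities. Complete or quasi-complete
#' separation is detected (fitted probabilities pinned at 0/1) and flagged
#' rather than silently returning divergent coefficients.
#'
#' @param features `data.frame` or matrix of numeric predictors (may have
#'   zero columns for an intercept-only model).
#' @param labels positive-class indicator.
#' @return list (class `logistic_fit`): coefficients, fitted probabilities,
#'   auc, converged, separation.
#' @export
fit_logistic <- function(features, labels) {
  labels <- as.logical(labels)
  y <- as.integer(labels)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least 2 subjects per class")
  features <- as.data.frame(features)
  dat <- data.frame(.y = y)
  if (ncol(features) > 0L) dat <- cbind(dat, features)
  form <- if (ncol(features) == 0L) .y ~ 1 else
    stats::as.formula(paste(".y ~", paste(names(features), collapse = " + ")))
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned_sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  p <- stats::fitted(fit)
  separation <- warned_sep || any(p < 1e-10) || any(p > 1 - 1e-10)
  if (!fit$converged && !separation)
    stop("logistic fit failed to converge (deviance ",
         format(fit$deviance), " after ", fit$iter, " iterations)")
  auc <- auc_concordance(p, labels)
  structure(list(coefficients = stats::coef(fit), fitted = p, auc = auc,
                 converged = fit$converged, separation = separation,
                 glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic fit: in-sample AUC", sprintf("%.3f", x$auc),
      if (x$separation) "[separation detected]" else "", "\n")
  print(x$coefficients)
  invisible(x)
}
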