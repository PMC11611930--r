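#' Kaplan-Meier fit with median survival
#'
#' Product-limit estimator (via the survival package) with the median
#' defined as the earliest time at which the survival curve drops to 0.5 or
#' below; NA when the curve never reaches 0.5 (heavily censored data).
#'
#' @param time follow-up times in days (> 0).
#' @param event 1 = death, 0 = censored.
#' @return list (class `km_fit`): time, surv, n_risk, n_event, median.
#' @export
km_fit <- function(time, event) {
  if (length(time) < 1L) stop("need at least one subject")
  if (any(time <= 0)) stop("survival times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- if (any(sf$surv <= 0.5)) min(sf$time[sf$surv <= 0.5]) else NA_real_
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, median = med, n = length(time)),
            class = "km_fit")
}

#' Log-rank test with Mantel-Haenszel hazard ratio
#'
#' Observed-minus-expected chi-square over the distinct event times with the
#' hypergeometric variance, for k >= 2 groups. For two groups the
#' Mantel-Haenszel hazard ratio (O1/E1)/(O2/E2) is reported with a 95% CI on
#' the log scale using se(log HR) = sqrt(1/E1 + 1/E2).
#'
#' @param time,event as in [km_fit()].
#' @param group group labels (>= 2 levels).
#' @return list (class `logrank_result`): chi2, df, p, observed, expected,
#'   and for two groups mantel_haenszel_hr with hr_ci_95.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 groups")
  if (any(time <= 0)) stop("survival times must be > 0")
  if (sum(event) < 1) stop("no events observed")
  lev <- levels(group)
  etimes <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(k), lev)
  V <- matrix(0, k, k, dimnames = list(lev, lev))
  for (t in etimes) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    n_g <- vapply(lev, function(g) sum(at_risk & group == g), numeric(1))
    d_g <- vapply(lev, function(g) sum(event == 1 & time == t & group == g),
                  numeric(1))
    e_g <- d_t * n_g / n_t
    O <- O + d_g
    E <- E + e_g
    if (n_t > 1) {
      c_t <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + c_t * (diag(n_g / n_t, k) - tcrossprod(n_g / n_t))
    }
  }
  idx <- seq_len(k - 1L)
  Vsub <- V[idx, idx, drop = FALSE]
  d <- (O - E)[idx]
  chi2 <- tryCatch(drop(t(d) %*% solve(Vsub, d)), error = function(e) {
    drop(t(d) %*% MASS_ginv(Vsub) %*% d)
  })
  p <- stats::pchisq(chi2, df = k - 1L, lower.tail = FALSE)
  out <- list(chi2 = chi2, df = k - 1L, p = p, observed = O, expected = E)
  if (k == 2L) {
    if (all(E > 0) && all(O > 0)) {
      hr <- (O[1] / E[1]) / (O[2] / E[2])
      se <- sqrt(1 / E[1] + 1 / E[2])
      ci <- exp(log(hr) + c(-1, 1) * stats::qnorm(0.975) * se)
    } else {
      # no events in one arm: the ratio degenerates to 0 or Inf and the
      # log-normal CI is undefined
      hr <- if (all(E > 0)) (O[1] / E[1]) / (O[2] / E[2]) else NA_real_
      ci <- c(NA_real_, NA_real_)
    }
    out$mantel_haenszel_hr <- unname(hr)
    out$hr_ci_95 <- unname(ci)
  }
  structure(out, class = "logrank_result")
}

# minimal Moore-Penrose fallback for singular log-rank variance matrices
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.3f (df %d), p = %.4g\n", x$chi2, x$df, x$p))
  if (!is.null(x$mantel_haenszel_hr))
    cat(sprintf("Mantel-Haenszel HR = %.2f (95%% CI %.2f-%.2f)\n",
                x$mantel_haenszel_hr, x$hr_ci_95[1], x$hr_ci_95[2]))
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Newton-Raphson, Efron correction for tied event
#' times) via the survival package, reporting per-covariate coefficients,
#' hazard ratios with Wald 95% CIs and p-values, the score test at beta = 0,
#' and flags for under-identification and monotone-likelihood divergence
#' (a covariate perfectly ordering the events).
#'
#' @param time,event as in [km_fit()].
#' @param covariates `data.frame` of numeric covariates.
#' @return list (class `cox_result`): table (coef, hr, ci_lo, ci_hi, se, p),
#'   loglik, score_chi2, converged, divergent, under_identified.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 1L) stop("need at least one covariate")
  if (any(time <= 0)) stop("survival times must be > 0")
  under_identified <- sum(event) < ncol(covariates)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(names(covariates), collapse = " + ")))
  warned <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-8, iter.max = 50)),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  # diverging fits can yield a non-PD information matrix; NaN se is flagged below
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  divergent <- any(grepl("infinite|did not converge|Loglik converged before",
                         warned)) || isTRUE(any(abs(beta) > 15, na.rm = TRUE))
  tab <- data.frame(
    covariate = names(beta),
    coef = unname(beta),
    hr = exp(unname(beta)),
    ci_lo = exp(unname(beta) - 1.96 * se),
    ci_hi = exp(unname(beta) + 1.96 * se),
    se = unname(se),
    p = 2 * stats::pnorm(-abs(unname(beta) / se))
  )
  constant <- vapply(covariates, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant)) {
    tab$coef[constant] <- 0
    tab$hr[constant] <- 1
    tab$se[constant] <- NA_real_
    tab$ci_lo[constant] <- tab$ci_hi[constant] <- tab$p[constant] <- NA_real_
  }
  structure(list(table = tab, loglik = fit$loglik,
                 score_chi2 = unname(fit$score),
                 converged = is.null(fit$info) && !divergent,
                 divergent = divergent,
                 under_identified = under_identified),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  print(x$table, digits = 4)
  if (x$divergent) cat("[monotone likelihood / divergence flagged]\n")
  invisible(x)
}
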