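test_that("Kaplan-Meier estimator matches hand product-limit results", {
  f <- km_fit(1:10, rep(1, 10))
  expect_equal(f$surv, seq(0.9, 0, by = -0.1), tolerance = 1e-12)
  expect_equal(f$median, 5)
  # no censoring: KM equals the empirical survival function
  expect_equal(f$surv, 1 - (1:10) / 10, tolerance = 1e-12)

  cens <- km_fit(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(cens$surv == 1))
  expect_true(is.na(cens$median))

  one <- km_fit(4, 1)
  expect_equal(one$surv, 0)
  expect_equal(one$median, 4)
  expect_error(km_fit(c(-1, 2), c(1, 1)), "> 0")
})

test_that("log-rank chi-square matches hand computation and survdiff", {
  # identical experience in both groups
  t0 <- rep(c(2, 4, 6), 2)
  e0 <- rep(1, 6)
  g0 <- rep(c("a", "b"), each = 3)
  r0 <- logrank_test(t0, e0, g0)
  expect_equal(r0$chi2, 0, tolerance = 1e-12)
  expect_equal(r0$mantel_haenszel_hr, 1, tolerance = 1e-12)

  # 6-subject example with hand-computable O/E:
  # group a: events at 1, 3; censored 5.  group b: events at 2, 4; censored 6.
  tt <- c(1, 3, 5, 2, 4, 6)
  ee <- c(1, 1, 0, 1, 1, 0)
  gg <- rep(c("a", "b"), each = 3)
  # t=1: risk 3a+3b, d=1 -> Ea += 1/2 ; t=2: risk 2a+3b, Ea += 2/5
  # t=3: risk 2a+2b, Ea += 1/2 ; t=4: risk 1a+2b, Ea += 1/3
  Ea <- 1 / 2 + 2 / 5 + 1 / 2 + 1 / 3
  r <- logrank_test(tt, ee, gg)
  expect_equal(unname(r$expected["a"]), Ea, tolerance = 1e-12)
  expect_equal(unname(r$observed["a"]), 2)
  sd_ref <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(r$chi2, unname(sd_ref$chisq), tolerance = 1e-10)
  # relabeling inverts the hazard ratio, chi2 unchanged
  r_sw <- logrank_test(tt, ee, factor(gg, levels = c("b", "a")))
  expect_equal(r_sw$chi2, r$chi2, tolerance = 1e-12)
  expect_equal(r_sw$mantel_haenszel_hr, 1 / r$mantel_haenszel_hr,
               tolerance = 1e-12)
  expect_true(r$hr_ci_95[1] <= r$mantel_haenszel_hr &&
                r$mantel_haenszel_hr <= r$hr_ci_95[2])
})

test_that("k-group log-rank matches survdiff on simulated subtypes", {
  set.seed(5)
  d <- simulate_metric_cohort(cohort_sim_spec(seed = 5L))
  d <- d[d$cohort == "tcia", ]
  r <- logrank_test(d$os_days, d$event, d$subtype)
  ref <- survival::survdiff(survival::Surv(d$os_days, d$event) ~ d$subtype)
  expect_equal(r$chi2, unname(ref$chisq), tolerance = 1e-8)
  expect_identical(r$df, 2L)
})

test_that("Mantel-Haenszel HR is consistent under proportional hazards", {
  set.seed(60)
  hrs <- replicate(200, {
    n <- 200
    g <- rep(c(1, 2), each = n / 2)
    rate <- ifelse(g == 1, 3e-3, 1e-3)   # rate ratio 3
    t_ev <- rexp(n, rate)
    t_c <- runif(n, 0, 1500)
    logrank_test(pmin(t_ev, t_c), as.integer(t_ev <= t_c), g)$mantel_haenszel_hr
  })
  expect_gt(median(hrs), 2.5)
  expect_lt(median(hrs), 3.6)
})

test_that("Cox regression: degenerate covariates, score-test equivalence", {
  tt <- c(2, 4, 6, 8, 10, 12)
  ee <- c(1, 1, 0, 1, 1, 0)
  cst <- cox_fit(tt, ee, data.frame(x = rep(1, 6)))
  expect_equal(cst$table$coef, 0)
  expect_true(is.na(cst$table$se))

  # binary covariate, no ties: score test at beta=0 equals log-rank chi2
  set.seed(14)
  n <- 60
  x <- rep(c(0, 1), each = n / 2)
  t_ev <- rexp(n, exp(0.8 * x) * 1e-3)
  t_c <- runif(n, 0, 2000)
  time <- pmin(t_ev, t_c); ev <- as.integer(t_ev <= t_c)
  stopifnot(!any(duplicated(time[ev == 1])))
  cf <- cox_fit(time, ev, data.frame(x = x))
  lr <- logrank_test(time, ev, x)
  expect_equal(cf$score_chi2, lr$chi2, tolerance = 1e-6)

  # a covariate perfectly ordering the events diverges and is flagged
  t_mono <- 1:20
  e_mono <- rep(1, 20)
  x_mono <- 1:20
  div <- cox_fit(t_mono, e_mono, data.frame(x = x_mono))
  expect_true(div$divergent)
})

test_that("Cox coefficients agree with coxph on multivariate input", {
  d <- simulate_metric_cohort(cohort_sim_spec(seed = 8L))
  d <- d[d$cohort == "tcia" & d$subtype == "IDHm-A", ]
  cf <- cox_fit(d$os_days, d$event, d[, c("nadc_tumor", "age")])
  ref <- survival::coxph(survival::Surv(os_days, event) ~ nadc_tumor + age,
                         data = d, ties = "efron")
  expect_equal(cf$table$coef, unname(coef(ref)), tolerance = 1e-8)
})
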