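#' Metric-level cohort simulation specification
#'
#' Emulates the cohort structure of a 105-lesion non-enhancing glioma series:
#' four groups — IDH-mutant astrocytoma with >= 25% T2FM-volume
#' ("mismatched"), IDHm-A with < 25% ("non-mismatched"), IDH-mutant
#' oligodendroglioma, IDH-wild-type glioma — with group-wise whole-tumor nADC
#' distributions ordered mismatched > non-mismatched > IDHm-O > IDHwt, a
#' strictly positive within-lesion T2FM-over-T2FNM nADC elevation, %T2FM
#' volumes consistent with group membership, log-normal tumor volumes,
#' exponential survival with heavy administrative censoring (worst survival
#' in IDHwt, best in IDHm-O), and an institutional subset that is fully
#' censored.
#'
#' @param n_per_group lesion counts for (IDHm-A >=25%, IDHm-A <25%, IDHm-O,
#'   IDHwt); default c(27, 38, 18, 22).
#' @param nadc_means,nadc_sds whole-tumor nADC normal parameters per group.
#' @param t2fm_means,t2fm_sds %T2FM-volume truncated-normal parameters per
#'   group (mismatched truncated to [25, 100], non-mismatched to [0, 25),
#'   others to [0, 100]).
#' @param delta_mean,delta_sd Gamma-distributed within-lesion nADC elevation
#'   of the T2FM over the T2FNM subregion (strictly positive).
#' @param volume_meanlog,volume_sdlog log-normal tumor volume (mL).
#' @param age_mean,age_sd age distribution, truncated to [18, 85].
#' @param surv_rates daily exponential event rates per subtype
#'   (IDHm-A, IDHm-O, IDHwt).
#' @param censor_horizon_days administrative censoring: uniform follow-up on
#'   (0, horizon].
#' @param tcia_fraction fraction of lesions flagged as the open-archive
#'   subset eligible for survival analysis; the remainder are fully censored.
#' @param seed default seed used by [simulate_metric_cohort()].
#' @export
cohort_sim_spec <- function(n_per_group = c(27L, 38L, 18L, 22L),
                            nadc_means = c(2.6, 2.1, 1.8, 1.6),
                            nadc_sds = rep(0.3, 4),
                            t2fm_means = c(45, 8, 8, 4),
                            t2fm_sds = c(12, 6, 6, 4),
                            delta_mean = 0.58, delta_sd = 0.2,
                            volume_meanlog = log(40), volume_sdlog = 0.7,
                            age_mean = 42, age_sd = 12,
                            surv_rates = c(`IDHm-A` = 7.3e-5,
                                           `IDHm-O` = 3e-5,
                                           IDHwt = 1.4e-3),
                            censor_horizon_days = 2600,
                            tcia_fraction = 0.7, seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 4L || any(n_per_group < 0L))
    stop("`n_per_group` must be 4 non-negative counts")
  if (any(nadc_sds < 0) || any(t2fm_sds < 0))
    stop("SDs must be >= 0")
  if (any(surv_rates <= 0)) stop("survival rates must be > 0")
  if (delta_mean < 0 || delta_sd < 0) stop("delta parameters must be >= 0")
  structure(as.list(environment()), class = "cohort_sim_spec")
}

group_levels <- c("IDHm-A>=25%", "IDHm-A<25%", "IDHm-O", "IDHwt")

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(pmin(hi, pmax(lo, rep(mean, n))))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate a metric-level cohort
#'
#' Draws one record per lesion: group, subtype, grade, age, tumor volume,
#' %T2FM-volume, whole-tumor and subregion median nADC, overall-survival time
#' and event flag, and cohort membership. Deterministic under a fixed seed.
#'
#' @param spec a [cohort_sim_spec()].
#' @param seed overrides `spec$seed`.
#' @return `data.frame` with one row per lesion.
#' @export
simulate_metric_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_per_group
  ntot <- sum(n)
  group <- factor(rep(group_levels, times = n), levels = group_levels)
  subtype <- c("IDHm-A", "IDHm-A", "IDHm-O", "IDHwt")[as.integer(group)]
  cols <- c("lesion_id", "group", "subtype", "grade", "age", "volume_ml",
            "pct_t2fm", "nadc_tumor", "nadc_t2fm", "nadc_t2fnm",
            "os_days", "event", "cohort")
  if (ntot == 0L) {
    out <- data.frame(lesion_id = character(0), group = factor(character(0),
                      levels = group_levels), subtype = character(0),
                      grade = integer(0), age = numeric(0),
                      volume_ml = numeric(0), pct_t2fm = numeric(0),
                      nadc_tumor = numeric(0), nadc_t2fm = numeric(0),
                      nadc_t2fnm = numeric(0), os_days = numeric(0),
                      event = integer(0), cohort = character(0))
    return(out[cols])
  }
  gi <- as.integer(group)

  nadc <- stats::rnorm(ntot, spec$nadc_means[gi], spec$nadc_sds[gi])
  pct <- numeric(ntot)
  for (g in 1:4) {
    sel <- gi == g
    pct[sel] <- rtruncnorm1(sum(sel), spec$t2fm_means[g], spec$t2fm_sds[g],
                            c(25, 0, 0, 0)[g], c(100, 25, 100, 100)[g])
  }
  # strictly positive mismatch-core elevation split around the tumor median
  if (spec$delta_sd > 0) {
    shape <- (spec$delta_mean / spec$delta_sd)^2
    rate <- spec$delta_mean / spec$delta_sd^2
    delta <- stats::rgamma(ntot, shape = shape, rate = rate)
  } else {
    delta <- rep(spec$delta_mean, ntot)
  }
  nadc_t2fm <- nadc + delta / 2
  nadc_t2fnm <- nadc - delta / 2

  volume <- stats::rlnorm(ntot, spec$volume_meanlog, spec$volume_sdlog)
  age <- rtruncnorm1(ntot, spec$age_mean, spec$age_sd, 18, 85)

  grade <- integer(ntot)
  is_a <- subtype == "IDHm-A"
  grade[is_a] <- sample(c(2L, 3L, 4L), sum(is_a), replace = TRUE,
                        prob = c(44, 20, 1))
  is_o <- subtype == "IDHm-O"
  grade[is_o] <- sample(c(2L, 3L), sum(is_o), replace = TRUE, prob = c(17, 1))
  grade[subtype == "IDHwt"] <- 4L

  rate <- spec$surv_rates[subtype]
  t_event <- stats::rexp(ntot, rate)
  t_censor <- stats::runif(ntot, 0, spec$censor_horizon_days)
  tcia <- stats::runif(ntot) < spec$tcia_fraction
  os <- pmin(t_event, t_censor)
  event <- as.integer(t_event <= t_censor)
  # institutional records are administratively censored in full
  event[!tcia] <- 0L
  os[!tcia] <- t_censor[!tcia]

  data.frame(
    lesion_id = sprintf("sim%03d", seq_len(ntot)),
    group = group, subtype = subtype, grade = grade, age = age,
    volume_ml = volume, pct_t2fm = pct,
    nadc_tumor = nadc, nadc_t2fm = nadc_t2fm, nadc_t2fnm = nadc_t2fnm,
    os_days = os, event = event,
    cohort = ifelse(tcia, "tcia", "institutional"),
    stringsAsFactors = FALSE
  )[cols]
}
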