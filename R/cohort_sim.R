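timepoint_pair <- function(x, name) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L) stop(sprintf("cohort_sim_config: %s must have length 1 or 2", name))
  names(x) <- c("24h", "1week")
  x
}

#' Configuration for the synthetic stroke cohort
#'
#' Generates a cohort with the covariate distributions of a thrombectomy-trial
#' population and a known linear model for follow-up net water uptake,
#'
#' \deqn{NWU_{FU} = B_0 + B_1 NWU_{BL} + B_2 IVT + \beta_r R + \sum_j \beta_j x_j + \varepsilon,}
#'
#' where `R` is the reperfusion-success indicator (eTICI at or above
#' `etici_threshold`) and the `x_j` are age, sex, baseline NIHSS, baseline
#' ASPECTS and onset-to-randomization time. Every injected coefficient is
#' returned in a ground-truth record so estimation can be validated by
#' parameter recovery. Defaults reproduce the study conditions: baseline NWU
#' log-normal with median 4.3% and IQR 2.1-6.8, P(eTICI>=2B) = 0.83,
#' P(eTICI>=2C) = 0.57, P(IVT) = 0.59, residual SD 7% NWU, and per-timepoint
#' effects typical of adjusted analyses in such cohorts (reperfusion -4.6 / -6.5,
#' IVT 1.3 / -0.7, age 0.01 / 0.02, male sex 1.9 / 0.6, NIHSS 0.1 / 0.1,
#' ASPECTS 0.2 / -0.1, onset-to-randomization 0.02 / 0.02 per minute).
#'
#' @param n_patients cohort size (>= 2).
#' @param intercept,coef_baseline,coef_ivt,coef_etici per-timepoint (24 h,
#'   1 week) coefficients; scalars are recycled. `coef_baseline` is B1 on the
#'   follow-up scale (the change-score model reports B1 - 1).
#' @param coef_covariates named list with per-timepoint effects `age`,
#'   `sex_male`, `nihss`, `aspects`, `onset` (% NWU per unit).
#' @param etici_threshold which dichotomization carries `coef_etici`
#'   (`"2B"` or `"2C"`).
#' @param residual_sd residual SD of follow-up NWU, % (>= 0).
#' @param p_etici2b,p_etici2c,p_ivt marginal probabilities; requires
#'   `p_etici2c <= p_etici2b`.
#' @param missing_rate MCAR cell-deletion rate applied by
#'   [inject_missingness()] after generation (0 = complete table).
#' @param seed integer RNG seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 115L,
                              intercept = c(0, 10),
                              coef_baseline = c(1, 1),
                              coef_ivt = c(1.3, -0.7),
                              coef_etici = c(-4.6, -6.5),
                              coef_covariates = list(age = c(0.01, 0.02),
                                                     sex_male = c(1.9, 0.6),
                                                     nihss = c(0.1, 0.1),
                                                     aspects = c(0.2, -0.1),
                                                     onset = c(0.02, 0.02)),
                              etici_threshold = c("2B", "2C"),
                              residual_sd = 7,
                              p_etici2b = 0.83, p_etici2c = 0.57, p_ivt = 0.59,
                              missing_rate = 0, seed = 1L) {
  etici_threshold <- match.arg(etici_threshold)
  if (n_patients < 2) stop("cohort_sim_config: n_patients must be >= 2")
  if (residual_sd < 0) stop("cohort_sim_config: residual_sd must be >= 0")
  probs <- c(p_etici2b = p_etici2b, p_etici2c = p_etici2c, p_ivt = p_ivt)
  if (any(probs < 0 | probs > 1))
    stop("cohort_sim_config: probabilities must lie in [0, 1]")
  if (p_etici2c > p_etici2b)
    stop("cohort_sim_config: p_etici2c cannot exceed p_etici2b")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("cohort_sim_config: missing_rate must lie in [0, 1)")
  need <- c("age", "sex_male", "nihss", "aspects", "onset")
  if (!all(need %in% names(coef_covariates)))
    stop("cohort_sim_config: coef_covariates needs ",
         paste(need, collapse = ", "))
  cc <- lapply(need, function(nm) timepoint_pair(coef_covariates[[nm]], nm))
  names(cc) <- need
  structure(list(n_patients = as.integer(n_patients),
                 intercept = timepoint_pair(intercept, "intercept"),
                 coef_baseline = timepoint_pair(coef_baseline, "coef_baseline"),
                 coef_ivt = timepoint_pair(coef_ivt, "coef_ivt"),
                 coef_etici = timepoint_pair(coef_etici, "coef_etici"),
                 coef_covariates = cc, etici_threshold = etici_threshold,
                 residual_sd = residual_sd, p_etici2b = p_etici2b,
                 p_etici2c = p_etici2c, p_ivt = p_ivt,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' eTICI reperfusion grades
#' @export
etici_levels <- c("0", "1", "2A", "2B", "2C", "3")

# Baseline NWU: log-normal matched to median 4.3 and IQR 2.1-6.8
# (meanlog = log(median); sdlog from the IQR of the log scale).
rlnorm_median_iqr <- function(n, med, q1, q3) {
  stats::rlnorm(n, meanlog = log(med),
                sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a patient cohort with known regression structure
#'
#' Covariates are drawn from parametric forms matched to a thrombectomy-trial
#' baseline table (age truncated normal, median 71, IQR 59-76; NIHSS and
#' ASPECTS bounded integers matched to IQRs 11-19 and 8-10; male sex 63%;
#' onset-to-randomization log-normal, median 92 min, IQR 70-140; baseline NWU
#' log-normal, median 4.3%, IQR 2.1-6.8). The eTICI ordinal is drawn so that
#' the two dichotomizations hit their marginal probabilities, splitting
#' uniformly within {0, 1, 2A} and {2C, 3}. Follow-up NWU obeys the linear
#' model exactly before residual noise and missingness.
#'
#' @param config A [cohort_sim_config()].
#' @return List: `cohort` (data.frame, one row per patient) and `truth`
#'   (every injected coefficient plus the config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  age <- rtrunc_norm(n, 71, (76 - 59) / (2 * stats::qnorm(0.75)), 18, 95)
  sex <- ifelse(stats::runif(n) < 0.63, "male", "female")
  nihss <- pmin(pmax(round(rtrunc_norm(
    n, 16, (19 - 11) / (2 * stats::qnorm(0.75)), 0, 42)), 0L), 42L)
  aspects <- pmin(pmax(round(rtrunc_norm(n, 9, 1.5, 0, 10)), 0L), 10L)
  onset <- rlnorm_median_iqr(n, 92, 70, 140)
  ivt <- as.integer(stats::runif(n) < config$p_ivt)
  p_lo <- (1 - config$p_etici2b) / 3          # 0, 1, 2A
  p_hi <- config$p_etici2c / 2                # 2C, 3
  probs <- c(p_lo, p_lo, p_lo, config$p_etici2b - config$p_etici2c, p_hi, p_hi)
  etici <- factor(sample(etici_levels, n, replace = TRUE, prob = probs),
                  levels = etici_levels, ordered = TRUE)
  nwu_bl <- rlnorm_median_iqr(n, 4.3, 2.1, 6.8)
  reperf <- dichotomize_etici(etici, config$etici_threshold)
  male <- as.integer(sex == "male")
  cc <- config$coef_covariates
  fu <- function(tp) {
    mu <- config$intercept[tp] + config$coef_baseline[tp] * nwu_bl +
      config$coef_ivt[tp] * ivt + config$coef_etici[tp] * reperf +
      cc$age[tp] * age + cc$sex_male[tp] * male + cc$nihss[tp] * nihss +
      cc$aspects[tp] * aspects + cc$onset[tp] * onset
    mu + stats::rnorm(n, 0, config$residual_sd)
  }
  cohort <- data.frame(subject_id = sprintf("P%04d", seq_len(n)),
                       age = age, sex = sex, nihss_baseline = nihss,
                       aspects_baseline = aspects,
                       onset_to_randomization = onset, ivt = ivt,
                       etici = etici, nwu_bl = nwu_bl,
                       nwu_24h = fu("24h"), nwu_1wk = fu("1week"),
                       stringsAsFactors = FALSE)
  if (config$missing_rate > 0)
    cohort <- inject_missingness(cohort, config$missing_rate,
                                 seed = config$seed + 1L)
  truth <- list(intercept = config$intercept,
                coef_baseline = config$coef_baseline,
                coef_ivt = config$coef_ivt, coef_etici = config$coef_etici,
                coef_covariates = cc, etici_threshold = config$etici_threshold,
                residual_sd = config$residual_sd, config = config)
  list(cohort = cohort, truth = truth)
}

#' Delete cohort cells completely at random
#'
#' Sets the expected fraction `rate` of eligible cells to `NA`, independently
#' at random (MCAR only; other mechanisms are rejected). Identifiers,
#' treatment assignment, reperfusion grade and the NWU outcome columns are
#' never deleted.
#'
#' @param table cohort data.frame from [simulate_cohort()].
#' @param rate deletion probability per cell, in \[0, 1).
#' @param mechanism must be `"MCAR"`.
#' @param seed integer RNG seed.
#' @param columns eligible columns; default the five clinical covariates
#'   (age, sex, NIHSS, ASPECTS, onset-to-randomization).
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, rate, mechanism = "MCAR", seed = 1L,
                               columns = c("age", "sex", "nihss_baseline",
                                           "aspects_baseline",
                                           "onset_to_randomization")) {
  if (!identical(mechanism, "MCAR"))
    stop("inject_missingness: only the MCAR mechanism is supported")
  if (rate < 0 || rate >= 1)
    stop("inject_missingness: rate must lie in [0, 1)")
  if (rate == 0) return(table)
  stopifnot(all(columns %in% names(table)))
  set.seed(seed)
  for (cl in columns) {
    hit <- stats::runif(nrow(table)) < rate
    table[[cl]][hit] <- NA
  }
  table
}
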