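#' Dichotomize an eTICI reperfusion grade
#'
#' Successful reperfusion is eTICI >= 2B; the stricter definition of
#' excellent/near-complete reperfusion is eTICI >= 2C.
#'
#' @param grade vector of grades in `0, 1, 2A, 2B, 2C, 3` (character, factor
#'   or ordered factor).
#' @param threshold `"2B"` or `"2C"`.
#' @return Integer 0/1 vector (`NA` preserved).
#' @examples
#' dichotomize_etici(c("2A", "2B", "2C", "3"), "2B")  # 0 1 1 1
#' dichotomize_etici(c("2B", "3"), "2C")              # 0 1
#' @export
dichotomize_etici <- function(grade, threshold = c("2B", "2C")) {
  threshold <- match.arg(threshold)
  g <- as.character(grade)
  bad <- !is.na(g) & !g %in% etici_levels
  if (any(bad))
    stop("dichotomize_etici: unknown grade(s): ",
         paste(unique(g[bad]), collapse = ", "))
  rank <- match(g, etici_levels)
  as.integer(rank >= match(threshold, etici_levels))
}

fu_column <- function(interval) {
  switch(interval, "24h" = "nwu_24h", "1week" = "nwu_1wk",
         stop("unknown interval: ", interval))
}

# Design variables for the ΔNWU models; exposure picks the reported term and
# (for adjusted fits) which eTICI dichotomization enters the model.
model_terms <- function(exposure, adjusted, baseline_adjusted) {
  etici_term <- if (exposure == "etici2c") "etici2c" else "etici2b"
  terms <- if (adjusted) {
    c("ivt", etici_term, "age", "sex_male", "nihss_baseline",
      "aspects_baseline", "onset_to_randomization")
  } else {
    switch(exposure, ivt = "ivt", etici2b = "etici2b", etici2c = "etici2c",
           stop("unknown exposure: ", exposure))
  }
  if (baseline_adjusted) c("nwu_bl", terms) else terms
}

#' Baseline-adjusted regression of NWU progression
#'
#' Fits ordinary least squares of follow-up NWU on baseline NWU plus the
#' exposure (and, when `adjusted`, age, sex, baseline NIHSS, baseline
#' ASPECTS, reperfusion status and onset-to-randomization time), then reports
#' the algebraically equivalent change-score parameterization
#' \deqn{\Delta NWU = B_0 + (B_1 - 1) NWU_{BL} + B_2 \cdot exposure + \dots:}
#' the baseline coefficient is shifted by exactly -1 and every other
#' coefficient, standard error and p-value is identical between the two
#' outcome scales.
#'
#' @param table cohort data.frame (columns as produced by
#'   [simulate_cohort()]); rows with missing model variables are dropped.
#' @param interval `"24h"` or `"1week"`.
#' @param exposure `"ivt"`, `"etici2b"` or `"etici2c"` — the reported term;
#'   adjusted models always contain IVT plus the matching eTICI indicator.
#' @param adjusted include the clinical adjustment set.
#' @param baseline_adjusted include baseline NWU as a regressor (the model
#'   derivation requires it; set `FALSE` for a raw change-score fit).
#' @param outcome fit on the `"followup"` NWU scale (default; reported on the
#'   change scale) or directly on the `"delta"` scale. Both give identical
#'   reported coefficients.
#' @return An `nwu_regression`: data.frame with columns `term`, `estimate`,
#'   `se`, `ci_lo`, `ci_hi`, `p`, plus attributes `n`, `df`, `label`,
#'   `exposure`.
#' @export
fit_delta_model <- function(table, interval = c("24h", "1week"),
                            exposure = c("ivt", "etici2b", "etici2c"),
                            adjusted = FALSE, baseline_adjusted = TRUE,
                            outcome = c("followup", "delta")) {
  interval <- match.arg(interval)
  exposure <- match.arg(exposure)
  outcome <- match.arg(outcome)
  df <- data.frame(table)
  df$sex_male <- as.integer(df$sex == "male")
  df$etici2b <- dichotomize_etici(df$etici, "2B")
  df$etici2c <- dichotomize_etici(df$etici, "2C")
  df$.y <- df[[fu_column(interval)]]
  if (outcome == "delta") df$.y <- df$.y - df$nwu_bl
  terms <- model_terms(exposure, adjusted, baseline_adjusted)
  keep <- stats::complete.cases(df[, c(".y", terms)])
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  if (n <= length(terms) + 1)
    stop("fit_delta_model: too few complete rows for the requested model")
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(terms) + 1)
    stop("fit_delta_model: rank-deficient design matrix")
  sm <- summary(fit)$coefficients
  est <- sm[, 1]; se <- sm[, 2]
  # report on the change scale: outcome NWU_FU differs from ΔNWU only by the
  # regressor NWU_BL, so only the baseline coefficient shifts (by -1)
  if (outcome == "followup" && baseline_adjusted)
    est["nwu_bl"] <- est["nwu_bl"] - 1
  dfree <- fit$df.residual
  tcrit <- stats::qt(0.975, dfree)
  res <- data.frame(term = rownames(sm), estimate = unname(est),
                    se = unname(se), ci_lo = unname(est - tcrit * se),
                    ci_hi = unname(est + tcrit * se),
                    p = unname(2 * stats::pt(-abs(est / se), dfree)),
                    row.names = NULL)
  # the intercept's p-value is against 0 on the change scale either way;
  # baseline term is tested against 0 on the change scale (i.e. B1 = 1)
  structure(res, class = c("nwu_regression", "data.frame"),
            n = n, df = dfree,
            label = sprintf("%s ΔNWU_%s (%s)",
                            if (adjusted) "multivariable" else "univariable",
                            interval, exposure),
            exposure = switch(exposure, ivt = "ivt", etici2b = "etici2b",
                              etici2c = "etici2c"))
}

#' Extract the exposure row of a fitted model
#' @param result An `nwu_regression`.
#' @return One-row data.frame.
#' @export
exposure_row <- function(result) {
  result[result$term == attr(result, "exposure"), , drop = FALSE]
}
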