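fit_or_pool <- function(tables, ...) {
  if (inherits(tables, "imputation_set")) {
    if (tables$m == 1L) return(fit_delta_model(tables$imputations[[1]], ...))
    fits <- lapply(tables$imputations, fit_delta_model, ...)
    pool_rubin(fits)
  } else {
    fit_delta_model(tables, ...)
  }
}

#' The full univariable + multivariable model set for NWU progression
#'
#' Fits (and, for an [mice_impute()] set, pools) the six univariable models —
#' IVT, eTICI>=2B and eTICI>=2C at 24 h and 1 week — and the four
#' multivariable models: the adjustment set (IVT, age, sex, baseline NIHSS,
#' baseline ASPECTS, onset-to-randomization time) with reperfusion entered as
#' eTICI>=2B, and the same set with the stricter eTICI>=2C definition, each
#' at both intervals. All models carry baseline NWU (toggleable) and are
#' reported on the change (ΔNWU) scale; significance is flagged at p < 0.05.
#'
#' @param tables an `imputation_set` or a single complete cohort data.frame.
#' @param baseline_adjusted include baseline NWU in every model (default
#'   `TRUE`, per the change-score derivation).
#' @return List: `results` (long data.frame with model metadata, one row per
#'   term) and `fits` (named list of `nwu_regression`).
#' @export
run_table2 <- function(tables, baseline_adjusted = TRUE) {
  specs <- list()
  for (interval in c("24h", "1week")) {
    for (expo in c("ivt", "etici2b", "etici2c"))
      specs[[paste("uni", expo, interval, sep = "_")]] <-
        list(interval = interval, exposure = expo, adjusted = FALSE)
    for (expo in c("etici2b", "etici2c"))
      specs[[paste("multi", expo, interval, sep = "_")]] <-
        list(interval = interval, exposure = expo, adjusted = TRUE)
  }
  fits <- list()
  rows <- list()
  for (nm in names(specs)) {
    s <- specs[[nm]]
    fit <- tryCatch(
      fit_or_pool(tables, interval = s$interval, exposure = s$exposure,
                  adjusted = s$adjusted, baseline_adjusted = baseline_adjusted),
      error = function(e) stop(sprintf("run_table2 [%s]: %s", nm,
                                       conditionMessage(e))))
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(model = nm, interval = s$interval,
                             exposure = s$exposure,
                             adjusted = s$adjusted, fit,
                             significant = fit$p < 0.05)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, fits = fits)
}
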