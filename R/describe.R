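fmt_med_iqr <- function(x, digits = 3) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%s (%s-%s)", signif(q[1], digits), signif(q[2], digits),
          signif(q[3], digits))
}

fmt_n_pct <- function(k, n) sprintf("%d (%.0f%%)", k, 100 * k / max(n, 1))

# Chi-square unless any expected cell count is below 5, then Fisher exact.
cat_test_p <- function(tab) {
  if (any(dim(tab) < 2)) return(NA_real_)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) stats::fisher.test(tab)$p.value
  else suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
}

#' Cohort descriptive table
#'
#' Baseline-characteristics summary in the conventional trial-table layout:
#' continuous variables as median (IQR) compared with the two-sided
#' Mann-Whitney U test; binary/categorical variables as counts (%) compared
#' with the chi-square test, switching to Fisher's exact test when any
#' expected cell count falls below 5.
#'
#' @param table cohort data.frame.
#' @param group `"ivt"` to compare treatment arms, `"none"` for overall only.
#' @param variables named character vector mapping column names to
#'   `"continuous"` or `"categorical"`; the default covers the simulated
#'   cohort columns.
#' @return data.frame: `variable`, `type`, `overall`, (per-group columns),
#'   `p_value`.
#' @export
describe_cohort <- function(table, group = c("ivt", "none"),
                            variables = c(age = "continuous",
                                          sex = "categorical",
                                          nihss_baseline = "continuous",
                                          aspects_baseline = "continuous",
                                          onset_to_randomization = "continuous",
                                          etici2b = "categorical",
                                          etici2c = "categorical",
                                          nwu_bl = "continuous",
                                          nwu_24h = "continuous",
                                          nwu_1wk = "continuous")) {
  group <- match.arg(group)
  df <- data.frame(table)
  if ("etici" %in% names(df)) {
    df$etici2b <- dichotomize_etici(df$etici, "2B")
    df$etici2c <- dichotomize_etici(df$etici, "2C")
  }
  variables <- variables[names(variables) %in% names(df)]
  grouped <- group != "none"
  if (grouped && !"ivt" %in% names(df))
    stop("describe_cohort: grouping column 'ivt' is missing")
  g <- if (grouped) factor(df$ivt, levels = c(0, 1),
                           labels = c("no_ivt", "ivt")) else NULL
  rows <- lapply(names(variables), function(v) {
    x <- df[[v]]
    type <- variables[[v]]
    if (type == "continuous") {
      x <- as.numeric(x)
      out <- data.frame(variable = v, type = type, overall = fmt_med_iqr(x))
      if (grouped) {
        out$no_ivt <- fmt_med_iqr(x[g == "no_ivt"])
        out$ivt <- fmt_med_iqr(x[g == "ivt"])
        out$p_value <- tryCatch(
          suppressWarnings(stats::wilcox.test(x ~ g)$p.value),
          error = function(e) NA_real_)
      }
    } else {
      pos <- if (is.numeric(x)) 1 else if ("male" %in% x) "male" else
        sort(unique(stats::na.omit(x)))[1]
      k <- sum(x == pos, na.rm = TRUE)
      out <- data.frame(variable = v, type = type,
                        overall = fmt_n_pct(k, sum(!is.na(x))))
      if (grouped) {
        k0 <- sum(x[g == "no_ivt"] == pos, na.rm = TRUE)
        k1 <- sum(x[g == "ivt"] == pos, na.rm = TRUE)
        out$no_ivt <- fmt_n_pct(k0, sum(!is.na(x[g == "no_ivt"])))
        out$ivt <- fmt_n_pct(k1, sum(!is.na(x[g == "ivt"])))
        out$p_value <- cat_test_p(table(x, g))
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
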