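# Chained-equations imputation with predictive mean matching and Rubin
# pooling. Implemented directly (linear algebra via QR) so the hot loop of
# m chains x iterations x columns stays fast at cohort scale.

# Bayesian linear regression draw + predictive mean matching (type-1 PMM).
# y observed on rows `obs`; X is the full predictor matrix (with intercept).
pmm_draw <- function(y, X, obs, k = 5L) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  qr_ <- qr(Xo)
  r <- qr_$rank
  piv <- qr_$pivot[seq_len(r)]
  beta <- qr.coef(qr_, yo)
  beta[is.na(beta)] <- 0
  dfres <- max(length(yo) - r, 1L)
  resid <- yo - as.vector(Xo %*% beta)
  sigma2 <- sum(resid^2) / stats::rchisq(1, dfres)
  R <- qr.R(qr_)[seq_len(r), seq_len(r), drop = FALSE]
  bdot <- beta
  bdot[piv] <- beta[piv] +
    backsolve(R, stats::rnorm(r)) * sqrt(sigma2)
  yhat_obs <- as.vector(Xo %*% beta)
  yhat_mis <- as.vector(X[!obs, , drop = FALSE] %*% bdot)
  # match each missing prediction to one of its k nearest observed
  # predictions; the k nearest by |yhat| lie inside a 2k window of the
  # sorted observed predictions, so the search is vectorized
  ord <- order(yhat_obs, method = "radix")
  ys <- yhat_obs[ord]
  yso <- yo[ord]
  nobs <- length(ys)
  nmis <- length(yhat_mis)
  k <- min(k, nobs)
  pos <- findInterval(yhat_mis, ys)
  offs <- seq(-k + 1L, k)
  cand <- outer(pos, offs, "+")
  cand[cand < 1L] <- 1L
  cand[cand > nobs] <- nobs
  d <- abs(matrix(ys[cand], nrow = nmis) - yhat_mis)
  # draw a target rank r ~ U{1..k} per row, then peel off the s-th smallest
  # distance in k vectorized sweeps
  target <- sample.int(k, nmis, replace = TRUE)
  pick <- integer(nmis)
  rows <- seq_len(nmis)
  for (s in seq_len(k)) {
    j <- max.col(-d, ties.method = "first")
    hit <- target == s
    pick[hit] <- j[hit]
    if (s < k) d[cbind(rows, j)] <- Inf
  }
  yso[cand[cbind(rows, pick)]]
}

# Logistic draw for a binary variable: fit on observed rows, perturb the
# coefficients by their asymptotic normal, draw Bernoulli outcomes.
logistic_draw <- function(y, X, obs) {
  fit <- suppressWarnings(stats::glm.fit(X[obs, , drop = FALSE], y[obs],
                                         family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  W <- fit$weights
  XtWX <- crossprod(X[obs, , drop = FALSE] * sqrt(pmax(W, 1e-8)))
  cov <- tryCatch(solve(XtWX), error = function(e) diag(1e-6, length(beta)))
  bdot <- beta + as.vector(t(chol(cov + diag(1e-10, nrow(cov)))) %*%
                             stats::rnorm(length(beta)))
  p <- stats::plogis(as.vector(X[!obs, , drop = FALSE] %*% bdot))
  stats::rbinom(sum(!obs), 1L, p)
}

# Numeric encoding of the cohort for the imputation models.
encode_cohort <- function(table) {
  vars <- setdiff(names(table), "subject_id")
  enc <- lapply(vars, function(v) {
    x <- table[[v]]
    if (v == "sex") as.integer(x == "male")
    else if (v == "etici") match(as.character(x), etici_levels)
    else as.numeric(x)
  })
  names(enc) <- vars
  do.call(cbind, enc)
}

decode_column <- function(v, x, proto) {
  if (v == "sex") ifelse(x == 1, "male", "female")
  else if (v == "etici") factor(etici_levels[round(x)], levels = etici_levels,
                                ordered = TRUE)
  else if (is.integer(proto)) as.integer(round(x))
  else x
}

#' Multiple imputation by chained equations
#'
#' Each incomplete variable is regressed on all other variables and refilled
#' iteratively: predictive mean matching (5 donors) for continuous and
#' bounded-integer variables, a Bayesian logistic draw for binaries. The m
#' chains start from independent random fills under distinct sub-seeds and
#' are iterated `iterations` times, giving m completed copies of the cohort;
#' observed cells are never altered.
#'
#' @param table cohort data.frame with `NA`s.
#' @param m number of imputations (default 20).
#' @param iterations chained-equation sweeps per chain (default 10).
#' @param seed integer; chain c uses sub-seed `seed + c`.
#' @return An `imputation_set`: list with `imputations` (m data.frames),
#'   `m`, `iterations`, `seed`, `missing_pattern`.
#' @export
mice_impute <- function(table, m = 20L, iterations = 10L, seed = 1L) {
  stopifnot(m >= 1, iterations >= 1)
  vars <- setdiff(names(table), "subject_id")
  miss <- vapply(table[vars], function(x) any(is.na(x)), logical(1))
  all_missing <- vapply(table[vars], function(x) all(is.na(x)), logical(1))
  if (any(all_missing))
    stop("mice_impute: column(s) entirely missing: ",
         paste(vars[all_missing], collapse = ", "))
  if (!any(miss)) {
    imps <- replicate(m, table, simplify = FALSE)
  } else {
    X0 <- encode_cohort(table)
    na_idx <- is.na(X0)
    targets <- vars[miss]
    binary <- vapply(vars, function(v)
      all(stats::na.omit(unique(X0[, v])) %in% c(0, 1)), logical(1))
    imps <- vector("list", m)
    for (ch in seq_len(m)) {
      set.seed(seed + ch)
      X <- X0
      for (v in targets) {  # initial fill: resample observed values
        o <- !na_idx[, v]
        X[!o, v] <- sample(X[o, v], sum(!o), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (v in targets) {
          o <- !na_idx[, v]
          pred <- cbind(1, X[, setdiff(vars, v), drop = FALSE])
          X[!o, v] <- if (binary[v]) logistic_draw(X[, v], pred, o)
                      else pmm_draw(X[, v], pred, o)
        }
      }
      out <- table
      for (v in targets)
        out[[v]][na_idx[, v]] <- decode_column(v, X[na_idx[, v], v],
                                               table[[v]])
      imps[[ch]] <- out
    }
  }
  structure(list(imputations = imps, m = as.integer(m),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 missing_pattern = is.na(table)),
            class = "imputation_set")
}

#' Pool regression results across imputations (Rubin's rules)
#'
#' Pooled estimate = mean of per-imputation estimates; total variance
#' T = Ubar + (1 + 1/m) B with Ubar the mean within-imputation variance and
#' B the between-imputation variance of the estimates; confidence intervals
#' and p-values use Barnard-Rubin small-sample degrees of freedom. When the
#' between-imputation variance is zero the pooled result degenerates to the
#' common single-fit result.
#'
#' @param results list of `nwu_regression` objects with identical term sets
#'   (length m >= 2), e.g. one fit per imputed copy.
#' @return A pooled `nwu_regression`.
#' @export
pool_rubin <- function(results) {
  m <- length(results)
  stopifnot(m >= 2)
  terms <- results[[1]]$term
  for (r in results)
    if (!identical(r$term, terms))
      stop("pool_rubin: term sets differ across imputations")
  est <- sapply(results, function(r) r$estimate)   # terms x m
  se2 <- sapply(results, function(r) r$se^2)
  qbar <- rowMeans(est)
  ubar <- rowMeans(se2)
  b <- apply(est, 1, stats::var)
  tvar <- ubar + (1 + 1 / m) * b
  df_com <- attr(results[[1]], "df")
  lambda <- ifelse(tvar > 0, (1 + 1 / m) * b / tvar, 0)
  df_old <- (m - 1) / pmax(lambda, 1e-12)^2
  df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  dfree <- ifelse(lambda < 1e-12, df_com,
                  pmax(df_old * df_obs / (df_old + df_obs), 1))
  se <- sqrt(tvar)
  tcrit <- stats::qt(0.975, dfree)
  out <- data.frame(term = terms, estimate = qbar, se = se,
                    ci_lo = qbar - tcrit * se, ci_hi = qbar + tcrit * se,
                    p = ifelse(se > 0, 2 * stats::pt(-abs(qbar / se), dfree),
                               NA_real_),
                    row.names = NULL)
  structure(out, class = c("nwu_regression", "data.frame"),
            n = attr(results[[1]], "n"), df = df_com, m = m,
            between_var = b,
            label = paste0(attr(results[[1]], "label"), " [pooled]"),
            exposure = attr(results[[1]], "exposure"))
}
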