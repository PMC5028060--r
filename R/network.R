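#' Build the lagged regression design
#'
#' One row per lag pair with all five lagged ratings present (rows with a
#' missing lagged item cannot enter any of the five models and are
#' dropped here); each fit additionally drops rows whose outcome rating
#' is missing (per-model casewise deletion). Optionally restricted to one
#' relapse state — stratification means fitting on the state's subset
#' only, not interaction terms.
#'
#' @param lag_pairs Output of [build_lag_pairs()].
#' @param state Optional state filter (one of [esm_states()]); `NULL`
#'   keeps all states.
#' @return Data frame of design rows (possibly empty): `calendar_day`,
#'   `state`, current ratings under the symptom names, lagged ratings as
#'   `lag_<symptom>`.
#' @export
build_design <- function(lag_pairs, state = NULL) {
  d <- lag_pairs
  if (!is.null(state)) {
    stopifnot(state %in% esm_states())
    d <- d[d$state == state, , drop = FALSE]
  }
  lag_cols <- paste0("lag_", esm_symptoms())
  complete <- rowSums(is.na(d[lag_cols])) == 0
  d <- d[complete, c("calendar_day", "state", esm_symptoms(), lag_cols),
         drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Fit one lagged symptom regression
#'
#' Ordinary least squares of the current level of one symptom on the
#' previous-assessment levels of all five symptoms, with the calendar day
#' as a linear de-trending covariate:
#' \deqn{y_t = B_0 + B_1\,\mathrm{lag}(y_1) + \dots + B_5\,\mathrm{lag}(y_5)
#'       + B_6\,\mathrm{day} + e}
#' Coefficients are on the raw 1--7 Likert scale (unstandardized). Rows
#' with a missing outcome are dropped; at least one more row than the
#' number of parameters is required, and a constant (zero-variance)
#' lagged column is a rank-deficiency error naming the column.
#'
#' @param rows Design rows from [build_design()].
#' @param outcome One of [esm_symptoms()].
#' @param detrend Include the calendar-day covariate (default `TRUE`).
#' @return List: `outcome`, `coef` (named length-5 lag coefficients),
#'   `intercept`, `time_coef` (`NA` if `detrend = FALSE`), `se`, `p`
#'   (named over the same terms), `n`, `sigma`, `r_squared`.
#' @export
fit_lagged_regression <- function(rows, outcome, detrend = TRUE) {
  stopifnot(outcome %in% esm_symptoms())
  lag_cols <- paste0("lag_", esm_symptoms())
  d <- rows[!is.na(rows[[outcome]]), , drop = FALSE]
  n_par <- 6L + as.integer(detrend)
  if (nrow(d) <= n_par) {
    stop("fit_lagged_regression: only ", nrow(d), " complete rows for '",
         outcome, "' but the model has ", n_par, " parameters", call. = FALSE)
  }
  for (col in c(lag_cols, if (detrend) "calendar_day")) {
    if (stats::var(d[[col]]) == 0) {
      stop("fit_lagged_regression: predictor '", col,
           "' is constant; design is rank-deficient", call. = FALSE)
    }
  }
  if (stats::var(d[[outcome]]) == 0) {
    # a constant outcome is fit exactly by the intercept; lm's R^2 would
    # be a 0/0 artefact, so flag it as undefined instead
    zero <- stats::setNames(rep(0, 5), esm_symptoms())
    return(list(outcome = outcome, coef = zero,
                intercept = d[[outcome]][1],
                time_coef = if (detrend) 0 else NA_real_,
                se = zero * NA_real_, p = zero * NA_real_,
                n = nrow(d), sigma = 0, r_squared = NA_real_))
  }
  fml <- stats::reformulate(c(lag_cols, if (detrend) "calendar_day"),
                            response = outcome)
  fit <- stats::lm(fml, data = d)
  if (fit$rank < n_par) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("fit_lagged_regression: design is rank-deficient (collinear term",
         if (length(dropped) > 1) "s", ": ",
         paste(dropped, collapse = ", "), ")", call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  lag_coef <- cf[lag_cols, "Estimate"]
  names(lag_coef) <- esm_symptoms()
  r2 <- summary(fit)$r.squared
  list(outcome = outcome,
       coef = lag_coef,
       intercept = unname(cf["(Intercept)", "Estimate"]),
       time_coef = if (detrend) unname(cf["calendar_day", "Estimate"]) else NA_real_,
       se = stats::setNames(cf[lag_cols, "Std. Error"], esm_symptoms()),
       p = stats::setNames(cf[lag_cols, "Pr(>|t|)"], esm_symptoms()),
       n = nrow(d),
       sigma = summary(fit)$sigma,
       r_squared = if (is.nan(r2)) NA_real_ else r2)
}

#' Estimate a state-stratified lag-1 symptom network
#'
#' Fits the five lagged regressions (one per symptom as outcome) on the
#' lag pairs of one relapse state — or on all states pooled — and
#' assembles the 25 coefficients into the directed weighted adjacency
#' matrix `W`, where `W[i, j]` is the coefficient of lagged symptom `j`
#' in the model for current symptom `i` (edge `j -> i`; the diagonal
#' holds the autoregressive self-loops). With
#' `method = "spearman_partial"` the entries are instead Spearman partial
#' correlations (see [spearman_partial_network()]).
#'
#' @param series A state-labeled [esm_series()].
#' @param state One of [esm_states()], or `NULL` for all states pooled.
#' @param method `"regression"` (default) or `"spearman_partial"`.
#' @param detrend Include the calendar-day covariate (regression method).
#' @param standardize Z-score the outcome and lagged columns within the
#'   fitted subset before the regression (default `FALSE`: raw Likert
#'   scale).
#' @param max_lag_minutes Passed to [build_lag_pairs()].
#' @return A `symptom_network` object: list with `method`, `state`,
#'   `symptoms`, `W` (5x5), and for the regression method `intercepts`,
#'   `time_coef`, `se`, `p` (5x5), `n` (per outcome), `r_squared`; for
#'   the Spearman method `p` and `n`.
#' @export
estimate_network <- function(series, state = NULL,
                             method = c("regression", "spearman_partial"),
                             detrend = TRUE, standardize = FALSE,
                             max_lag_minutes = Inf) {
  method <- match.arg(method)
  if (method == "spearman_partial") {
    return(spearman_partial_network(series, state,
                                    max_lag_minutes = max_lag_minutes))
  }
  pairs <- build_lag_pairs(series, max_lag_minutes = max_lag_minutes)
  rows <- build_design(pairs, state)
  syms <- esm_symptoms()
  if (standardize) {
    for (col in c(syms, paste0("lag_", syms))) {
      rows[[col]] <- as.numeric(scale(rows[[col]]))
    }
  }
  W <- se <- p <- matrix(NA_real_, 5, 5, dimnames = list(syms, syms))
  intercepts <- time_coef <- r2 <- n <- stats::setNames(rep(NA_real_, 5), syms)
  for (i in seq_along(syms)) {
    f <- fit_lagged_regression(rows, syms[i], detrend = detrend)
    W[i, ] <- f$coef; se[i, ] <- f$se; p[i, ] <- f$p
    intercepts[i] <- f$intercept; time_coef[i] <- f$time_coef
    r2[i] <- f$r_squared; n[i] <- f$n
  }
  structure(list(method = "regression", state = state %||% "all",
                 symptoms = syms, W = W, intercepts = intercepts,
                 time_coef = time_coef, se = se, p = p, n = n,
                 r_squared = r2, detrend = detrend,
                 standardized = standardize),
            class = "symptom_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman partial-correlation sensitivity network
#'
#' Rank-based analogue of the regression network: `W[i, j]` is the
#' Spearman partial correlation between current symptom `i` and lagged
#' symptom `j`, conditioning on the remaining four lagged symptoms and
#' the calendar day — the same adjustment set as the regression. All
#' columns are rank-transformed (average ranks for ties), both target
#' columns are residualized on the conditioning set, and the partial
#' correlation is the correlation of the residuals. Being rank-based, the network is
#' invariant to strictly increasing transforms of any symptom.
#' Two-sided p-values use the t approximation with `n - 7` degrees of
#' freedom.
#'
#' @inheritParams estimate_network
#' @return A `symptom_network` object with `method = "spearman_partial"`.
#' @export
spearman_partial_network <- function(series, state = NULL,
                                     max_lag_minutes = Inf) {
  pairs <- build_lag_pairs(series, max_lag_minutes = max_lag_minutes)
  rows <- build_design(pairs, state)
  syms <- esm_symptoms()
  lag_cols <- paste0("lag_", syms)
  W <- p <- matrix(NA_real_, 5, 5, dimnames = list(syms, syms))
  n <- stats::setNames(rep(NA_real_, 5), syms)
  for (i in seq_along(syms)) {
    d <- rows[!is.na(rows[[syms[i]]]), c(syms[i], lag_cols, "calendar_day"),
              drop = FALSE]
    k <- 5L  # conditioning variables: 4 other lags + calendar_day
    if (nrow(d) <= k + 2L) {
      stop("spearman_partial_network: only ", nrow(d),
           " complete rows for '", syms[i], "'", call. = FALSE)
    }
    for (col in names(d)) {
      if (stats::var(d[[col]]) == 0) {
        stop("spearman_partial_network: column '", col,
             "' has zero variance", call. = FALSE)
      }
    }
    R <- apply(d, 2, rank)
    ry <- R[, 1]
    for (j in seq_len(5)) {
      Z <- cbind(1, R[, c(1 + setdiff(seq_len(5), j), 7)])
      qz <- qr(Z)
      res_y <- qr.resid(qz, ry)
      res_x <- qr.resid(qz, R[, 1 + j])
      r <- sum(res_y * res_x) / sqrt(sum(res_y^2) * sum(res_x^2))
      r <- min(1, max(-1, r))
      tstat <- r * sqrt((nrow(d) - 2 - k) /
                          max(1 - r^2, .Machine$double.eps))
      W[i, j] <- r
      p[i, j] <- 2 * stats::pt(-abs(tstat), df = nrow(d) - 2 - k)
    }
    n[i] <- nrow(d)
  }
  structure(list(method = "spearman_partial", state = state %||% "all",
                 symptoms = syms, W = W, p = p, n = n),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  cat("Symptom network (", x$method, ", state: ", x$state, ")\n", sep = "")
  cat("W[i, j] = edge j(t-1) -> i(t); n =",
      paste(unique(x$n), collapse = "/"), "\n")
  print(round(x$W, 3))
  invisible(x)
}
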