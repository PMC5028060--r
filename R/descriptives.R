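#' Per-state descriptive summary of symptom ratings
#'
#' Mean and sample (n-1) standard deviation of the answered, non-missing
#' beep-level ratings of each symptom, stratified by relapse state — the
#' severity-by-state descriptive table. States with no observations for a
#' symptom yield `NA` cells (undefined, not zero); a single observation
#' yields a defined mean and an undefined sd.
#'
#' @param series A state-labeled [esm_series()].
#' @return Data frame with `state`, `symptom`, `n`, `mean`, `sd`, plus an
#'   attribute `n_beeps` (answered beeps per state).
#' @export
state_summary <- function(series) {
  if (!"state" %in% names(series)) {
    stop("state_summary: series must be state-labeled", call. = FALSE)
  }
  a <- as.data.frame(series)[series$answered == 1L, , drop = FALSE]
  out <- expand.grid(symptom = esm_symptoms(), state = esm_states(),
                     stringsAsFactors = FALSE)[, 2:1]
  out$n <- 0L; out$mean <- NA_real_; out$sd <- NA_real_
  for (r in seq_len(nrow(out))) {
    v <- a[[out$symptom[r]]][a$state == out$state[r]]
    v <- v[!is.na(v)]
    out$n[r] <- length(v)
    if (length(v) >= 1) out$mean[r] <- mean(v)
    if (length(v) >= 2) out$sd[r] <- stats::sd(v)
  }
  attr(out, "n_beeps") <- table(factor(a$state, levels = esm_states()))
  out
}

#' Contrast a symptom's level between two relapse states
#'
#' Welch two-sample t comparison (unequal variances) of beep-level
#' ratings, two-sided. The statistic is oriented as `state_b` minus
#' `state_a`: a positive statistic and direction `"b>a"` mean the symptom
#' is rated higher in `state_b`.
#'
#' @param series A state-labeled [esm_series()].
#' @param symptom One of [esm_symptoms()].
#' @param state_a,state_b Two of [esm_states()].
#' @return Data frame row: `symptom`, `state_a`, `state_b`, `mean_a`,
#'   `mean_b`, `statistic`, `df`, `p_value`, `direction` (`"b>a"`,
#'   `"a>b"` or `"none"`).
#' @export
compare_states <- function(series, symptom, state_a, state_b) {
  stopifnot(symptom %in% esm_symptoms(),
            state_a %in% esm_states(), state_b %in% esm_states())
  a <- as.data.frame(series)[series$answered == 1L, , drop = FALSE]
  va <- a[[symptom]][a$state == state_a]; va <- va[!is.na(va)]
  vb <- a[[symptom]][a$state == state_b]; vb <- vb[!is.na(vb)]
  if (length(va) < 2 || length(vb) < 2) {
    stop("compare_states: need >= 2 observations in each state (have ",
         length(va), " and ", length(vb), ")", call. = FALSE)
  }
  tt <- stats::t.test(vb, va, var.equal = FALSE)
  stat <- unname(tt$statistic)
  data.frame(symptom = symptom, state_a = state_a, state_b = state_b,
             mean_a = mean(va), mean_b = mean(vb),
             statistic = stat, df = unname(tt$parameter),
             p_value = tt$p.value,
             direction = if (stat > 0) "b>a" else if (stat < 0) "a>b" else "none")
}

#' Day-level mean symptom series
#'
#' Mean of the answered, non-missing ratings per calendar day per symptom
#' (the day-level severity curves); days with no usable ratings yield
#' `NA`.
#'
#' @param series An [esm_series()].
#' @return Data frame with `calendar_day`, `day_index`, `state` (if
#'   labeled), `n_answered`, and one mean column per symptom.
#' @export
day_level_series <- function(series) {
  df <- as.data.frame(series)
  days <- unique(df[c("calendar_day", "day_index")])
  days <- days[order(days$calendar_day), , drop = FALSE]
  a <- df[df$answered == 1L, , drop = FALSE]
  days$n_answered <- as.integer(
    table(factor(a$calendar_day, levels = days$calendar_day)))
  for (s in esm_symptoms()) {
    m <- tapply(a[[s]], factor(a$calendar_day, levels = days$calendar_day),
                mean, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    days[[s]] <- as.numeric(m)
  }
  if ("state" %in% names(df)) {
    days$state <- df$state[match(days$calendar_day, df$calendar_day)]
  }
  rownames(days) <- NULL
  days
}

# Shared one-way ANOVA helper: value ~ state over >= 2 groups.
.state_anova <- function(value, state) {
  keep <- !is.na(value)
  value <- value[keep]; state <- droplevels(factor(state[keep]))
  if (nlevels(state) < 2) {
    stop("ANOVA needs observations in at least two states", call. = FALSE)
  }
  if (any(table(state) < 2)) {
    stop("ANOVA needs >= 2 observations per state", call. = FALSE)
  }
  av <- stats::anova(stats::lm(value ~ state))
  list(F = av[1, "F value"], p = av[1, "Pr(>F)"],
       df = c(av[1, "Df"], av[2, "Df"]))
}

#' Compare within-day symptom variability across states
#'
#' For each symptom, computes the within-day sample standard deviation of
#' answered ratings (days with at least two usable ratings), then a
#' one-way ANOVA of these day-level sds across the relapse states — the
#' check that moment-to-moment variability, not just level, is (or is
#' not) state-dependent.
#'
#' @param series A state-labeled [esm_series()].
#' @return Data frame with `symptom`, `F`, `p_value`, `df1`, `df2`,
#'   `n_days`.
#' @export
day_sd_by_state_anova <- function(series) {
  if (!"state" %in% names(series)) {
    stop("day_sd_by_state_anova: series must be state-labeled", call. = FALSE)
  }
  a <- as.data.frame(series)[series$answered == 1L, , drop = FALSE]
  out <- data.frame(symptom = esm_symptoms(), F = NA_real_,
                    p_value = NA_real_, df1 = NA_integer_,
                    df2 = NA_integer_, n_days = NA_integer_)
  for (r in seq_len(nrow(out))) {
    s <- out$symptom[r]
    sds <- tapply(a[[s]], a$calendar_day, function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2) stats::sd(v) else NA_real_
    })
    st <- a$state[match(names(sds), as.character(a$calendar_day))]
    keep <- !is.na(sds)
    res <- .state_anova(as.numeric(sds[keep]), st[keep])
    out$F[r] <- res$F; out$p_value[r] <- res$p
    out$df1[r] <- res$df[1]; out$df2[r] <- res$df[2]
    out$n_days[r] <- sum(keep)
  }
  out
}

#' Compare answered beeps per day across states
#'
#' One-way ANOVA of the number of answered beeps per monitored day across
#' relapse states — the check that completion is not biased by severity —
#' plus per-state mean and range of the daily counts.
#'
#' @param series A state-labeled [esm_series()].
#' @return List with `F`, `p_value`, `df1`, `df2` and `per_state` (data
#'   frame: `state`, `n_days`, `mean`, `min`, `max`).
#' @export
beeps_per_day_anova <- function(series) {
  if (!"state" %in% names(series)) {
    stop("beeps_per_day_anova: series must be state-labeled", call. = FALSE)
  }
  df <- as.data.frame(series)
  counts <- stats::aggregate(answered ~ calendar_day + state, data = df, FUN = sum)
  per_state <- do.call(rbind, lapply(esm_states(), function(st) {
    v <- counts$answered[counts$state == st]
    data.frame(state = st, n_days = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               min = if (length(v)) min(v) else NA_integer_,
               max = if (length(v)) max(v) else NA_integer_)
  }))
  rownames(per_state) <- NULL
  res <- .state_anova(counts$answered, counts$state)
  list(F = res$F, p_value = res$p, df1 = res$df[1], df2 = res$df[2],
       per_state = per_state)
}

#' Completion statistics
#'
#' Total answered beeps, the answered fraction of all scheduled beeps,
#' and the per-monitored-day mean, sd and range of answered counts.
#'
#' @param series An [esm_series()].
#' @return List with `n_answered`, `n_scheduled`, `n_days`, `fraction`,
#'   `per_day_mean`, `per_day_sd`, `per_day_min`, `per_day_max`.
#' @export
completion_stats <- function(series) {
  df <- as.data.frame(series)
  per_day <- tapply(df$answered, df$day_index, sum)
  list(n_answered = sum(df$answered),
       n_scheduled = nrow(df),
       n_days = length(per_day),
       fraction = sum(df$answered) / nrow(df),
       per_day_mean = mean(per_day),
       per_day_sd = stats::sd(per_day),
       per_day_min = as.integer(min(per_day)),
       per_day_max = as.integer(max(per_day)))
}
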