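# Small hand-built series for unit tests.

# One monitored day per element of `days`: each element is a list with
# fields answered (0/1 vector) and optional per-symptom rating vectors
# (default constant 4 where answered), dose (default 350).
make_series <- function(days, validate = TRUE) {
  syms <- esm_symptoms()
  rows <- lapply(seq_along(days), function(d) {
    spec <- days[[d]]
    nb <- length(spec$answered)
    times <- seq(480, by = 90, length.out = nb)
    df <- data.frame(
      calendar_day = if (!is.null(spec$calendar_day)) spec$calendar_day else d,
      day_index = d,
      beep_index = seq_len(nb),
      scheduled_time = times,
      answered = as.integer(spec$answered),
      dose_mg = if (!is.null(spec$dose)) spec$dose else 350L
    )
    for (s in syms) {
      v <- if (!is.null(spec[[s]])) spec[[s]] else
        ifelse(spec$answered == 1L, 4L, NA_integer_)
      v[spec$answered == 0L] <- NA_integer_
      df[[s]] <- as.integer(v)
    }
    df
  })
  esm_series(do.call(rbind, rows), validate = validate)
}

# Paper-frame generator config with overridable pieces; small helper so
# tests state only what they vary. Shorter-than-study runs without an
# explicit plan get a proportionally scaled two-episode plan (the default
# 201-day plan would not fit).
test_config <- function(..., seed = 1L) {
  args <- list(...)
  n <- args$n_monitored_days
  if (!is.null(n) && n < 201 && !"state_plan" %in% names(args)) {
    args$state_plan <- data.frame(
      state = c("impending_relapse", "full_relapse"),
      start_day = as.integer(round(c(0.2, 0.5) * n)),
      duration_days = as.integer(pmax(1, round(c(0.15, 0.25) * n)))
    )
  }
  do.call(synthetic_config, c(args, list(seed = seed)))
}

# Single-state dynamics helpers: diagonal lag matrix, mid-scale mean.
uniform_truth <- function(diag_val = 0.3, mu = rep(4, 5), sigma = rep(1.2, 5)) {
  syms <- esm_symptoms()
  A <- diag(diag_val, 5); dimnames(A) <- list(syms, syms)
  cc <- as.numeric((diag(5) - A) %*% mu); names(cc) <- syms
  names(sigma) <- syms
  list(A = stats::setNames(rep(list(A), 3), esm_states()),
       c = stats::setNames(rep(list(cc), 3), esm_states()),
       sigma = stats::setNames(rep(list(sigma), 3), esm_states()))
}

# Plan that assigns every monitored day to one state.
all_days_plan <- function(state, n_days) {
  if (state == "stable") return(NULL)
  data.frame(state = state, start_day = 1L, duration_days = as.integer(n_days))
}
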