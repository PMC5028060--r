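#' Construct and validate an ESM beep-level series
#'
#' An `esm_series` is a data frame with one row per scheduled beep and
#' columns `calendar_day` (days since study start, >= 1; drives
#' de-trending), `day_index` (monitored-day counter, >= 1), `beep_index`
#' (1..beeps per day), `scheduled_time` (minutes since midnight),
#' `answered` (0/1), one integer 1--7 rating column per symptom (NA =
#' missing; all NA when unanswered; item-level NA allowed when answered),
#' and `dose_mg` (daily clozapine dose). An optional `state` column is
#' added by [derive_states()].
#'
#' Validation enforces the sampling frame: scheduled times within
#' 7:30 AM--10:30 PM, within-day gaps between 10 minutes and 3 hours,
#' ratings in 1..7, unanswered beeps fully missing, rows sorted by
#' (`calendar_day`, `scheduled_time`), and a constant dose within each
#' calendar day.
#'
#' @param df Data frame with the columns above.
#' @param subject Optional subject label stored as an attribute.
#' @param validate Check invariants (default `TRUE`).
#' @return The validated data frame with class `esm_series`.
#' @export
esm_series <- function(df, subject = "subject-1", validate = TRUE) {
  required <- c("calendar_day", "day_index", "beep_index", "scheduled_time",
                "answered", esm_symptoms(), "dose_mg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("esm_series: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)
  df$answered <- as.integer(df$answered)
  if (validate) .validate_esm(df)
  ord <- order(df$calendar_day, df$scheduled_time)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "subject") <- subject
  class(df) <- c("esm_series", "data.frame")
  df
}

.validate_esm <- function(df) {
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop("esm_series validation: ", what, " (row",
           if (length(rows) > 1) "s", " ",
           paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) ", ...", ")", call. = FALSE)
    }
  }
  if (!is.numeric(df$scheduled_time) || anyNA(df$scheduled_time)) {
    stop("esm_series validation: scheduled_time must be numeric and non-missing",
         call. = FALSE)
  }
  bad(df$scheduled_time < .esm_window[1] | df$scheduled_time > .esm_window[2],
      sprintf("scheduled_time outside the %d-%d min sampling window",
              .esm_window[1], .esm_window[2]))
  bad(!(df$answered %in% c(0L, 1L)), "answered must be 0 or 1")
  bad(df$calendar_day < 1 | df$day_index < 1 | df$beep_index < 1,
      "day/beep indices must be >= 1")
  for (s in esm_symptoms()) {
    v <- df[[s]]
    bad(!is.na(v) & (v < 1 | v > 7 | v != round(v)),
        paste0("rating '", s, "' outside the 1-7 Likert range"))
    bad(df$answered == 0L & !is.na(v),
        paste0("unanswered beep carries a rating for '", s, "'"))
  }
  # within-day invariants, in time order
  ord <- order(df$calendar_day, df$scheduled_time)
  d <- df[ord, , drop = FALSE]
  same_day <- diff(d$calendar_day) == 0
  gaps <- diff(d$scheduled_time)[same_day]
  gap_rows <- which(same_day) + 1L
  if (any(gaps < .esm_gap_bounds[1] - 1e-9 | gaps > .esm_gap_bounds[2] + 1e-9)) {
    offending <- gap_rows[gaps < .esm_gap_bounds[1] - 1e-9 |
                            gaps > .esm_gap_bounds[2] + 1e-9]
    stop("esm_series validation: within-day beep gap outside [",
         .esm_gap_bounds[1], ", ", .esm_gap_bounds[2], "] minutes (row",
         if (length(offending) > 1) "s", " ",
         paste(utils::head(offending, 10), collapse = ", "), ")",
         call. = FALSE)
  }
  n_per_day <- table(d$calendar_day)
  if (any(n_per_day > 10)) {
    stop("esm_series validation: more than 10 beeps on calendar day ",
         names(n_per_day)[which(n_per_day > 10)[1]], call. = FALSE)
  }
  dose_var <- tapply(d$dose_mg, d$calendar_day, function(x) length(unique(x)))
  if (any(dose_var > 1)) {
    stop("esm_series validation: dose_mg varies within calendar day ",
         names(dose_var)[which(dose_var > 1)[1]], call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a beep-level ESM series from CSV
#'
#' Expects (after applying `column_map`) the columns documented in
#' [esm_series()]. Empty fields are missing ratings; `answered` is 0/1.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical
#'   column names to the file's column names, e.g.
#'   `c(down = "feeling_down")`, for foreign files.
#' @param subject Subject label.
#' @return An [esm_series()].
#' @export
read_esm_csv <- function(path, column_map = NULL, subject = "subject-1") {
  if (!file.exists(path)) stop("read_esm_csv: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("read_esm_csv: column_map names absent column '", src, "'",
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  required <- c("calendar_day", "day_index", "beep_index", "scheduled_time",
                "answered", esm_symptoms(), "dose_mg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("read_esm_csv: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    # header-only file: read.csv cannot infer types from zero rows
    for (col in c("calendar_day", "day_index", "beep_index", "scheduled_time",
                  "dose_mg")) df[[col]] <- numeric(0)
    df$answered <- integer(0)
    for (col in esm_symptoms()) df[[col]] <- integer(0)
  }
  if (!is.numeric(df$scheduled_time)) {
    stop("read_esm_csv: unparseable scheduled_time column (must be numeric ",
         "minutes since midnight)", call. = FALSE)
  }
  st <- if ("state" %in% names(df)) df$state else NULL
  out <- esm_series(df[required], subject = subject)
  if (!is.null(st)) out$state <- st[order(df$calendar_day, df$scheduled_time)]
  out
}

#' Write an ESM series to CSV
#'
#' Missing ratings are written as empty fields; the round trip
#' `read_esm_csv(write_esm_csv(s))` reproduces `s` exactly, including
#' missingness.
#'
#' @param series An [esm_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esm_csv <- function(series, path) {
  cols <- c("calendar_day", "day_index", "beep_index", "scheduled_time",
            "answered", esm_symptoms(), "dose_mg")
  if ("state" %in% names(series)) cols <- c(cols, "state")
  utils::write.csv(as.data.frame(series)[cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Default dose-to-state map
#'
#' The patient-specific operationalisation of severity: the maintenance
#' clozapine dose of 350 mg/day marks the stable state, the collaborative
#' increase to 400 mg/day an impending relapse, and to 450 mg/day a full
#' relapse.
#'
#' @return Named character vector: names are doses in mg, values state
#'   labels.
#' @export
default_dose_state_map <- function() {
  c("350" = "stable", "400" = "impending_relapse", "450" = "full_relapse")
}

#' Label each beep with the relapse state implied by its daily dose
#'
#' Deterministic and idempotent; the dose (hence the state) is constant
#' within a calendar day. A dose absent from the map is an error: the
#' state definition is total only on the configured dose levels.
#'
#' @param series An [esm_series()].
#' @param dose_state_map Named character vector (dose -> state); default
#'   [default_dose_state_map()].
#' @return The series with a `state` column (factor with levels
#'   [esm_states()]).
#' @export
derive_states <- function(series, dose_state_map = default_dose_state_map()) {
  key <- as.character(series$dose_mg)
  unmapped <- !key %in% names(dose_state_map)
  if (any(unmapped)) {
    i <- which(unmapped)[1]
    stop("derive_states: dose ", series$dose_mg[i],
         " mg on calendar day ", series$calendar_day[i],
         " is not in the dose-state map", call. = FALSE)
  }
  states <- unname(dose_state_map[key])
  if (!all(states %in% esm_states())) {
    stop("derive_states: dose-state map contains unknown state label(s): ",
         paste(setdiff(unique(states), esm_states()), collapse = ", "),
         call. = FALSE)
  }
  series$state <- factor(states, levels = esm_states())
  series
}

#' Build within-day lag pairs
#'
#' The regression unit: each answered beep that has an earlier answered
#' beep on the same calendar day is paired with the immediately preceding
#' answered beep of that day (regardless of missed scheduled beeps in
#' between). Pairs never span nights. When every answered beep is
#' item-complete, the number of pairs equals the number of answered beeps
#' minus the number of days with at least one answered beep.
#'
#' @param series A state-labeled [esm_series()] (see [derive_states()]).
#' @param max_lag_minutes Optional upper bound on the pair's time gap;
#'   default `Inf` (all same-day lags are kept).
#' @return Data frame with one row per pair: `calendar_day`, `day_index`,
#'   `state`, previous/current `beep_index` and `scheduled_time`,
#'   `gap_minutes`, current ratings under the symptom names and lagged
#'   ratings as `lag_<symptom>`.
#' @export
build_lag_pairs <- function(series, max_lag_minutes = Inf) {
  if (!"state" %in% names(series)) {
    stop("build_lag_pairs: series must be state-labeled; run derive_states() first",
         call. = FALSE)
  }
  a <- as.data.frame(series)[series$answered == 1L, , drop = FALSE]
  if (nrow(a) < 2) return(.empty_lag_pairs())
  a <- a[order(a$calendar_day, a$scheduled_time), , drop = FALSE]
  prev_idx <- c(NA_integer_, seq_len(nrow(a) - 1L))
  same_day <- c(FALSE, diff(a$calendar_day) == 0)
  keep <- same_day
  curr <- a[keep, , drop = FALSE]
  prev <- a[prev_idx[keep], , drop = FALSE]
  gap <- curr$scheduled_time - prev$scheduled_time
  ok <- gap <= max_lag_minutes
  curr <- curr[ok, , drop = FALSE]; prev <- prev[ok, , drop = FALSE]
  gap <- gap[ok]
  out <- data.frame(
    calendar_day = curr$calendar_day,
    day_index = curr$day_index,
    state = curr$state,
    prev_beep_index = prev$beep_index,
    curr_beep_index = curr$beep_index,
    prev_time = prev$scheduled_time,
    curr_time = curr$scheduled_time,
    gap_minutes = gap
  )
  for (s in esm_symptoms()) {
    out[[s]] <- curr[[s]]
    out[[paste0("lag_", s)]] <- prev[[s]]
  }
  rownames(out) <- NULL
  out
}

.empty_lag_pairs <- function() {
  out <- data.frame(
    calendar_day = integer(0), day_index = integer(0),
    state = factor(character(0), levels = esm_states()),
    prev_beep_index = integer(0), curr_beep_index = integer(0),
    prev_time = numeric(0), curr_time = numeric(0), gap_minutes = numeric(0)
  )
  for (s in esm_symptoms()) {
    out[[s]] <- integer(0)
    out[[paste0("lag_", s)]] <- integer(0)
  }
  out
}

#' Segment the monitored days into state episodes
#'
#' An episode is a maximal run of consecutive monitored days (by
#' `day_index`) sharing the same state; its duration is counted in
#' monitored days, and its `start_day`/`end_day` record the calendar days
#' of the run's first and last monitored day. Episode durations therefore
#' sum to the number of monitored days.
#'
#' @param series A state-labeled [esm_series()].
#' @return List with `episodes` (data frame: `state`, `start_day`,
#'   `end_day`, `start_day_index`, `end_day_index`, `duration_days`) and
#'   `summary` (per non-stable state: episode count, mean duration, min,
#'   max).
#' @export
segment_episodes <- function(series) {
  if (!"state" %in% names(series)) {
    stop("segment_episodes: series must be state-labeled", call. = FALSE)
  }
  days <- unique(data.frame(day_index = series$day_index,
                            calendar_day = series$calendar_day,
                            state = as.character(series$state)))
  days <- days[order(days$day_index), , drop = FALSE]
  r <- rle(days$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  episodes <- data.frame(
    state = factor(r$values, levels = esm_states()),
    start_day = days$calendar_day[starts],
    end_day = days$calendar_day[ends],
    start_day_index = days$day_index[starts],
    end_day_index = days$day_index[ends],
    duration_days = r$lengths
  )
  summ <- do.call(rbind, lapply(setdiff(esm_states(), "stable"), function(st) {
    dur <- episodes$duration_days[episodes$state == st]
    data.frame(state = st, n_episodes = length(dur),
               mean_duration = if (length(dur)) mean(dur) else NA_real_,
               min_duration = if (length(dur)) min(dur) else NA_integer_,
               max_duration = if (length(dur)) max(dur) else NA_integer_)
  }))
  rownames(summ) <- NULL
  list(episodes = episodes, summary = summ)
}
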