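#' Configure the synthetic ESM generator
#'
#' The generator emulates the study's sampling frame: `n_monitored_days`
#' monitored days (default 201), `monitored_days_per_week` (default 4,
#' spread over the week), `beeps_per_day` random signals (default 10)
#' scheduled within 7:30 AM--10:30 PM with consecutive gaps of 10--180
#' minutes, per-beep completion probability (default 0.469 = 943/2010),
#' and a small per-item missingness probability among answered beeps.
#' Symptom dynamics are a state-dependent lag-1 vector autoregression on a
#' latent scale, discretized to the 1--7 Likert scale by rounding and
#' clamping:
#' \deqn{x_k = c_s + A_s x_{k-1} + \tau d + \epsilon,\qquad
#'       \epsilon \sim N(0, \mathrm{diag}(\sigma_s^2))}
#' where `d` is the calendar day (the linear-trend covariate; `tau = 0` by
#' default) and `s` the day's relapse state. The first beep of each day is
#' drawn from the state's stationary distribution (`overnight = "reset"`,
#' the default) or propagated from the previous day's last beep
#' (`"carry"`).
#'
#' @param n_monitored_days Number of monitored days.
#' @param monitored_days_per_week Monitored days per 7-day week.
#' @param beeps_per_day Scheduled beeps per monitored day.
#' @param window_minutes Sampling window, minutes since midnight.
#' @param gap_bounds_minutes Bounds on consecutive within-day gaps.
#' @param completion_prob Per-beep answer probability; either a scalar or
#'   a named vector over [esm_states()] for state-dependent completion.
#' @param item_missing_prob Probability that an individual item is missing
#'   on an answered beep.
#' @param state_plan Data frame (`state`, `start_day`, `duration_days`)
#'   of relapse episodes in monitored days (see [default_state_plan()]),
#'   or `NULL` for an all-stable year.
#' @param A,c,sigma Per-state dynamics: named lists over [esm_states()] of
#'   5x5 lag matrices (entry `[i, j]` = effect of symptom j at t-1 on
#'   symptom i at t), length-5 intercepts, and length-5 innovation SDs.
#'   Defaults are [default_truth()].
#' @param tau Length-5 linear trend slope per calendar day (default 0).
#' @param overnight `"reset"` or `"carry"` (first beep of a day).
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @return A `synthetic_config` list, validated for feasibility (the
#'   minimum gaps must fit the window) and stationarity (spectral radius
#'   of each `A` < 1).
#' @export
synthetic_config <- function(n_monitored_days = 201,
                             monitored_days_per_week = 4,
                             beeps_per_day = 10,
                             window_minutes = c(450, 1350),
                             gap_bounds_minutes = c(10, 180),
                             completion_prob = 943 / 2010,
                             item_missing_prob = 0.004,
                             state_plan = default_state_plan(),
                             A = NULL, c = NULL, sigma = NULL,
                             tau = rep(0, 5),
                             overnight = c("reset", "carry"),
                             seed = 1L) {
  truth <- default_truth()
  if (is.null(A)) A <- truth$A
  if (is.null(c)) c <- truth$c
  if (is.null(sigma)) sigma <- truth$sigma
  overnight <- match.arg(overnight)
  cfg <- list(n_monitored_days = as.integer(n_monitored_days),
              monitored_days_per_week = as.integer(monitored_days_per_week),
              beeps_per_day = as.integer(beeps_per_day),
              window_minutes = as.numeric(window_minutes),
              gap_bounds_minutes = as.numeric(gap_bounds_minutes),
              completion_prob = completion_prob,
              item_missing_prob = item_missing_prob,
              state_plan = state_plan,
              A = A, c = c, sigma = sigma, tau = as.numeric(tau),
              overnight = overnight, seed = as.integer(seed))
  .validate_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

.validate_config <- function(cfg) {
  w <- cfg$window_minutes; g <- cfg$gap_bounds_minutes; B <- cfg$beeps_per_day
  if (g[1] <= 0 || g[2] < g[1]) {
    stop("synthetic_config: invalid gap bounds", call. = FALSE)
  }
  if ((B - 1) * g[1] > (w[2] - w[1])) {
    stop("synthetic_config: infeasible schedule: ", B, " beeps need at least ",
         (B - 1) * g[1], " min of minimum gaps but the window is only ",
         w[2] - w[1], " min wide", call. = FALSE)
  }
  cp <- cfg$completion_prob
  if (any(cp <= 0) || any(cp > 1)) {
    stop("synthetic_config: completion_prob must lie in (0, 1]", call. = FALSE)
  }
  if (length(cp) > 1 && !all(esm_states() %in% names(cp))) {
    stop("synthetic_config: state-dependent completion_prob must be named over ",
         "all three states", call. = FALSE)
  }
  if (cfg$monitored_days_per_week < 1 || cfg$monitored_days_per_week > 7) {
    stop("synthetic_config: monitored_days_per_week must be in 1..7", call. = FALSE)
  }
  for (st in esm_states()) {
    A <- cfg$A[[st]]
    if (is.null(A) || !all(dim(A) == c(5, 5))) {
      stop("synthetic_config: A$", st, " must be a 5x5 matrix", call. = FALSE)
    }
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho >= 1) {
      stop("synthetic_config: lag matrix for state '", st,
           "' is non-stationary (spectral radius ", signif(rho, 4), " >= 1)",
           call. = FALSE)
    }
    if (length(cfg$c[[st]]) != 5 || length(cfg$sigma[[st]]) != 5) {
      stop("synthetic_config: c$", st, " and sigma$", st,
           " must have length 5", call. = FALSE)
    }
  }
  if (!is.null(cfg$state_plan)) .validate_plan(cfg$state_plan, cfg$n_monitored_days)
  invisible(TRUE)
}

.validate_plan <- function(plan, n_days) {
  stopifnot(all(c("state", "start_day", "duration_days") %in% names(plan)))
  if (nrow(plan) == 0) return(invisible(TRUE))
  if (!all(plan$state %in% esm_states())) {
    stop("state_plan: unknown state label", call. = FALSE)
  }
  ends <- plan$start_day + plan$duration_days - 1L
  if (any(plan$start_day < 1) || any(ends > n_days)) {
    stop("state_plan: episode extends outside the monitored period", call. = FALSE)
  }
  p <- plan[order(plan$start_day), , drop = FALSE]
  if (nrow(p) > 1 &&
      any(p$start_day[-1] <= (p$start_day + p$duration_days - 1L)[-nrow(p)])) {
    stop("state_plan: overlapping episodes", call. = FALSE)
  }
  invisible(TRUE)
}

#' Default relapse-episode plan
#'
#' Four full-relapse episodes of 4, 15, 25 and 25 monitored days (mean
#' 17.25, range 4--25) and two impending-relapse episodes of 7 and 31 days
#' (mean 19, range 7--31), interleaved with stable periods over 201
#' monitored days — matching the reported episode counts, mean durations
#' and ranges of the study year.
#'
#' @return Data frame with `state`, `start_day` (monitored-day index) and
#'   `duration_days`.
#' @export
default_state_plan <- function() {
  data.frame(
    state = c("impending_relapse", "full_relapse", "full_relapse",
              "impending_relapse", "full_relapse", "full_relapse"),
    start_day = c(25L, 45L, 70L, 95L, 135L, 165L),
    duration_days = c(7L, 4L, 15L, 31L, 25L, 25L)
  )
}

#' Randomly placed relapse-episode plan
#'
#' Draws episode durations uniformly from the given ranges and places the
#' episodes at random non-overlapping positions (with at least one stable
#' day between episodes).
#'
#' @param n_monitored_days Length of the monitored period.
#' @param n_full,n_impending Number of full / impending relapse episodes.
#' @param full_duration_range,impending_duration_range Inclusive duration
#'   ranges in monitored days.
#' @return A state-plan data frame as in [default_state_plan()].
#' @export
auto_state_plan <- function(n_monitored_days = 201,
                            n_full = 4, n_impending = 2,
                            full_duration_range = c(4, 25),
                            impending_duration_range = c(7, 31)) {
  dur <- c(sample(full_duration_range[1]:full_duration_range[2], n_full,
                  replace = TRUE),
           sample(impending_duration_range[1]:impending_duration_range[2],
                  n_impending, replace = TRUE))
  st <- c(rep("full_relapse", n_full), rep("impending_relapse", n_impending))
  ord <- sample(length(dur))
  dur <- dur[ord]; st <- st[ord]
  for (attempt in 1:1000) {
    starts <- sort(sample(seq_len(n_monitored_days), length(dur)))
    ends <- starts + dur - 1L
    if (all(ends <= n_monitored_days) &&
        (length(starts) < 2 || all(starts[-1] > ends[-length(ends)] + 1L))) {
      return(data.frame(state = st, start_day = starts, duration_days = dur))
    }
  }
  stop("auto_state_plan: could not place episodes without overlap", call. = FALSE)
}

#' Default state-dependent dynamics
#'
#' Ground-truth lag matrices, intercepts and innovation SDs used as
#' generator defaults. They encode the qualitative network the analysis is
#' meant to detect: in the stable state a positive down--paranoia loop, a
#' negative relaxed--paranoia loop, a moderate negative relaxed-to-voices
#' edge (-0.16) and a moderate positive down-to-loss-of-control edge
#' (0.21); connectivity grows in the impending state; in full relapse
#' paranoia becomes the hub (strong outgoing edges to every other
#' symptom). Intercepts are chosen so the stationary means track the
#' reported per-state severity pattern (down and loss of control higher
#' and relaxed lower in full relapse; voices slightly lower in the
#' impending state).
#'
#' @return List with per-state `A`, `c`, `sigma` and the stationary mean
#'   targets `mu`.
#' @export
default_truth <- function() {
  syms <- esm_symptoms()
  mk <- function(diag_val, edges) {
    A <- diag(diag_val, 5)
    dimnames(A) <- list(syms, syms)
    for (e in edges) A[e[[1]], e[[2]]] <- e[[3]]
    A
  }
  A_stable <- mk(0.25, list(
    list("down", "paranoia", 0.20), list("paranoia", "down", 0.20),
    list("paranoia", "relaxed", -0.20), list("relaxed", "paranoia", -0.20),
    list("hearing_voices", "relaxed", -0.16),
    list("loss_of_control", "down", 0.21)))
  A_imp <- mk(0.30, list(
    list("down", "paranoia", 0.25), list("paranoia", "down", 0.25),
    list("paranoia", "relaxed", -0.25), list("relaxed", "paranoia", -0.25),
    list("hearing_voices", "relaxed", -0.20),
    list("loss_of_control", "down", 0.25),
    list("hearing_voices", "paranoia", 0.15),
    list("loss_of_control", "paranoia", 0.15)))
  A_full <- mk(0.35, list(
    list("down", "paranoia", 0.40), list("loss_of_control", "paranoia", 0.40),
    list("hearing_voices", "paranoia", 0.40), list("relaxed", "paranoia", -0.40),
    list("paranoia", "down", 0.20), list("paranoia", "hearing_voices", 0.20),
    list("down", "relaxed", -0.20), list("relaxed", "down", -0.20)))
  mu <- list(stable = c(2.1, 1.6, 2.8, 5.0, 4.0),
             impending_relapse = c(2.0, 1.4, 2.5, 4.7, 4.0),
             full_relapse = c(3.2, 2.2, 3.4, 4.8, 2.9))
  A <- list(stable = A_stable, impending_relapse = A_imp, full_relapse = A_full)
  cc <- lapply(esm_states(), function(st) {
    v <- as.numeric((diag(5) - A[[st]]) %*% mu[[st]]); names(v) <- syms; v
  })
  names(cc) <- esm_states()
  sig <- c(1.4, 1.2, 1.8, 1.4, 1.2); names(sig) <- syms
  sigma <- list(stable = sig, impending_relapse = sig, full_relapse = sig)
  for (st in esm_states()) names(mu[[st]]) <- syms
  list(A = A, c = cc, sigma = sigma, mu = mu)
}

#' Sample within-day beep schedules
#'
#' Sequential gap sampling with feasibility truncation: the first beep is
#' uniform over the times that leave room for the remaining minimum gaps;
#' each subsequent gap is uniform on `[min_gap, min(max_gap, slack)]`
#' where the slack keeps the remaining beeps inside the window. Every
#' sampled day therefore satisfies the window and gap invariants by
#' construction, and the sampler has full support over the feasible set.
#'
#' @param config A [synthetic_config()].
#' @param n_days Number of days to sample.
#' @return Numeric matrix `n_days x beeps_per_day` of scheduled times in
#'   minutes since midnight, strictly increasing within a row.
#' @export
sample_beep_schedule <- function(config, n_days) {
  B <- config$beeps_per_day
  w <- config$window_minutes; g <- config$gap_bounds_minutes
  times <- matrix(NA_real_, n_days, B)
  times[, 1] <- stats::runif(n_days, w[1], w[2] - (B - 1) * g[1])
  if (B > 1) {
    for (k in 2:B) {
      slack <- w[2] - (B - k) * g[1] - times[, k - 1]
      upper <- pmin(g[2], slack)
      times[, k] <- times[, k - 1] + stats::runif(n_days, g[1], upper)
    }
  }
  times
}

#' Expand the state plan into a per-day dose and state schedule
#'
#' Stable fills every monitored day not covered by a planned episode;
#' doses follow the inverse of [default_dose_state_map()] (350 / 400 /
#' 450 mg).
#'
#' @param config A [synthetic_config()].
#' @return Data frame with `day_index`, `calendar_day`, `state`,
#'   `dose_mg`.
#' @export
sample_state_schedule <- function(config) {
  n <- config$n_monitored_days
  state <- rep("stable", n)
  plan <- config$state_plan
  if (!is.null(plan) && nrow(plan) > 0) {
    .validate_plan(plan, n)
    for (i in seq_len(nrow(plan))) {
      idx <- plan$start_day[i] + seq_len(plan$duration_days[i]) - 1L
      state[idx] <- plan$state[i]
    }
  }
  dose_of <- c(stable = 350L, impending_relapse = 400L, full_relapse = 450L)
  data.frame(day_index = seq_len(n),
             calendar_day = .monitored_calendar_days(n, config$monitored_days_per_week),
             state = factor(state, levels = esm_states()),
             dose_mg = unname(dose_of[state]))
}

# Calendar-day positions of monitored days: m days spread over each 7-day
# week (e.g. m = 4 -> weekly offsets 1, 3, 5, 7).
.monitored_calendar_days <- function(n_days, m) {
  offsets <- unique(round(seq(1, 7, length.out = m)))
  week <- (seq_len(n_days) - 1L) %/% m
  pos <- (seq_len(n_days) - 1L) %% m + 1L
  as.integer(7L * week + offsets[pos])
}

# Stationary distribution of x = c + A x + tau*d + eps for one state.
.stationary <- function(A, cc, sigma, tau, day) {
  mu <- solve(diag(5) - A, cc + tau * day)
  S <- matrix(solve(diag(25) - kronecker(A, A), as.numeric(diag(sigma^2))), 5, 5)
  list(mu = mu, chol = t(chol(S + 1e-12 * diag(5))))
}

#' Simulate a synthetic ESM series with known ground truth
#'
#' Runs the latent state-dependent VAR(1) at every scheduled beep
#' (answered or not), discretizes to Likert ratings by
#' `clamp(round(x), 1, 7)`, applies per-beep completion and per-item
#' missingness, and returns both the observed series and the ground truth
#' (dynamics, realized state schedule, latent values) for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return List with `series` (a state-labeled [esm_series()]) and
#'   `truth` (list: `A`, `c`, `sigma`, `tau`, `schedule`, `latent`).
#' @export
simulate_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  syms <- esm_symptoms()
  B <- config$beeps_per_day
  sched <- sample_state_schedule(config)
  n_days <- nrow(sched)
  times <- sample_beep_schedule(config, n_days)

  # latent dynamics; 5 x (n_days * B), beeps of a day contiguous
  latent <- matrix(NA_real_, 5, n_days * B)
  tau <- config$tau
  if (config$overnight == "reset") {
    # days are conditionally independent given state -> vectorize per state
    for (st in esm_states()) {
      d_idx <- which(sched$state == st)
      if (length(d_idx) == 0) next
      A <- config$A[[st]]; cc <- config$c[[st]]; sg <- config$sigma[[st]]
      D <- length(d_idx)
      days_cal <- sched$calendar_day[d_idx]
      statc <- .stationary(A, cc, sg, rep(0, 5), 0)
      X <- statc$chol %*% matrix(stats::rnorm(5 * D), 5, D) +
        solve(diag(5) - A, outer(cc, rep(1, D)) + outer(tau, days_cal))
      cols <- (d_idx - 1L) * B + 1L
      latent[, cols] <- X
      if (B > 1) {
        for (k in 2:B) {
          eps <- sg * matrix(stats::rnorm(5 * D), 5, D)
          X <- cc + A %*% X + outer(tau, days_cal) + eps
          latent[, cols + k - 1L] <- X
        }
      }
    }
  } else {
    x <- NULL
    for (d in seq_len(n_days)) {
      st <- as.character(sched$state[d])
      A <- config$A[[st]]; cc <- config$c[[st]]; sg <- config$sigma[[st]]
      day_cal <- sched$calendar_day[d]
      for (k in seq_len(B)) {
        if (is.null(x)) {
          statc <- .stationary(A, cc, sg, tau, day_cal)
          x <- statc$mu + statc$chol %*% stats::rnorm(5)
        } else {
          x <- cc + A %*% x + tau * day_cal + sg * stats::rnorm(5)
        }
        latent[, (d - 1L) * B + k] <- x
      }
    }
  }

  ratings <- pmin(pmax(round(latent), 1), 7)
  cp <- config$completion_prob
  p_by_beep <- if (length(cp) == 1) rep(cp, n_days * B) else
    rep(unname(cp[as.character(sched$state)]), each = B)
  answered <- stats::rbinom(n_days * B, 1L, p_by_beep)
  item_na <- matrix(stats::runif(5 * n_days * B) < config$item_missing_prob,
                    5, n_days * B)

  df <- data.frame(
    calendar_day = rep(sched$calendar_day, each = B),
    day_index = rep(sched$day_index, each = B),
    beep_index = rep(seq_len(B), times = n_days),
    scheduled_time = as.numeric(t(times)),
    answered = answered,
    dose_mg = rep(sched$dose_mg, each = B)
  )
  for (i in seq_along(syms)) {
    v <- as.integer(ratings[i, ])
    v[answered == 0L | item_na[i, ]] <- NA_integer_
    df[[syms[i]]] <- v
  }
  df <- df[c("calendar_day", "day_index", "beep_index", "scheduled_time",
             "answered", syms, "dose_mg")]
  series <- derive_states(esm_series(df, subject = "synthetic"))
  truth <- list(A = config$A, c = config$c, sigma = config$sigma,
                tau = config$tau, schedule = sched,
                latent = t(latent))
  colnames(truth$latent) <- syms
  list(series = series, truth = truth)
}

#' Write the generator ground truth to JSON
#'
#' Matrices are stored row-major in the canonical symptom order; the
#' latent series is omitted unless `include_latent = TRUE`.
#'
#' @param truth Ground-truth list from [simulate_series()].
#' @param path Output path.
#' @param include_latent Store the latent series too (can be large).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, include_latent = FALSE) {
  out <- list(
    symptoms = esm_symptoms(),
    A = lapply(truth$A, function(m) {
      d <- as.data.frame(m); rownames(d) <- NULL; d
    }),
    c = truth$c, sigma = truth$sigma, tau = truth$tau,
    schedule = truth$schedule
  )
  if (include_latent) out$latent <- as.data.frame(truth$latent)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
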