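test_that("state summary computes per-state means and sample sds", {
  s <- derive_states(make_series(list(
    list(answered = c(1, 1, 1), down = c(2, 2, 5), dose = 350L),
    list(answered = c(1, 0, 0), down = c(3, NA, NA), dose = 450L)
  )))
  ss <- state_summary(s)
  stable_down <- ss[ss$state == "stable" & ss$symptom == "down", ]
  expect_equal(stable_down$n, 3L)
  expect_equal(stable_down$mean, 3)
  expect_equal(stable_down$sd, sd(c(2, 2, 5)))  # 1.7320508

  # a single observation has a defined mean but an undefined sd
  full_down <- ss[ss$state == "full_relapse" & ss$symptom == "down", ]
  expect_equal(full_down$n, 1L)
  expect_equal(full_down$mean, 3)
  expect_true(is.na(full_down$sd))

  # absent states are undefined cells, not zeros
  imp <- ss[ss$state == "impending_relapse", ]
  expect_true(all(imp$n == 0L) && all(is.na(imp$mean)) && all(is.na(imp$sd)))
})

test_that("pooled mean equals the n-weighted mean of state means", {
  series <- simulate_series(test_config(seed = 21))$series
  ss <- state_summary(series)
  for (s in esm_symptoms()) {
    rows <- ss[ss$symptom == s & ss$n > 0, ]
    pooled <- sum(rows$mean * rows$n) / sum(rows$n)
    v <- series[[s]][series$answered == 1L]
    expect_equal(pooled, mean(v, na.rm = TRUE))
    expect_true(all(rows$mean >= 1 & rows$mean <= 7))
  }
})

test_that("state contrasts are Welch t tests with oriented direction", {
  s <- derive_states(make_series(list(
    list(answered = rep(1, 4), down = c(2, 3, 4, 5), dose = 350L),
    list(answered = rep(1, 4), down = c(2, 3, 4, 5), dose = 450L)
  )))
  same <- compare_states(s, "down", "stable", "full_relapse")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(14)
  g_a <- pmin(pmax(round(rnorm(300, 2, 1)), 1), 7)
  g_b <- pmin(pmax(round(rnorm(100, 3, 1)), 1), 7)
  s2 <- derive_states(make_series(c(
    lapply(split(g_a, ceiling(seq_along(g_a) / 10)), function(v)
      list(answered = rep(1, length(v)), down = v, dose = 350L)),
    lapply(split(g_b, ceiling(seq_along(g_b) / 10)), function(v)
      list(answered = rep(1, length(v)), down = v, dose = 450L))
  )))
  up <- compare_states(s2, "down", "stable", "full_relapse")
  expect_lt(up$p_value, 0.001)
  expect_equal(up$direction, "b>a")

  flipped <- compare_states(s2, "down", "full_relapse", "stable")
  expect_equal(flipped$statistic, -up$statistic)
  expect_equal(flipped$p_value, up$p_value)
  expect_equal(flipped$direction, "a>b")

  expect_error(compare_states(s, "down", "stable", "impending_relapse"),
               ">= 2 observations")
})

test_that("day-level series averages answered ratings per day", {
  s <- make_series(list(
    list(answered = c(1, 1, 1), down = c(7, 7, 3)),
    list(answered = c(0, 0), down = c(NA, NA))
  ))
  d <- day_level_series(s)
  expect_equal(d$down, c(17 / 3, NA))
  expect_equal(d$n_answered, c(3L, 0L))

  const <- make_series(list(list(answered = c(1, 1)), list(answered = c(1, 1))))
  expect_equal(day_level_series(const)$down, c(4, 4))
})

test_that("day-sd ANOVA: equal sd distributions give F = 0; two groups give F = t^2", {
  mk_day <- function(vals, dose) list(answered = rep(1, length(vals)),
                                      down = vals, loss_of_control = vals,
                                      paranoia = vals, hearing_voices = vals,
                                      relaxed = vals, dose = dose)
  # identical multisets of within-day sds in both states -> group means equal
  s <- derive_states(make_series(list(
    mk_day(c(2, 4), 350L), mk_day(c(1, 5), 350L),
    mk_day(c(3, 5), 450L), mk_day(c(2, 6), 450L)
  )))
  res <- day_sd_by_state_anova(s)
  expect_true(all(abs(res$F) < 1e-12))
  expect_true(all(res$p_value > 0.999))

  # two groups: one-way F equals the squared pooled-variance t statistic
  s2 <- derive_states(make_series(list(
    mk_day(c(2, 4), 350L), mk_day(c(1, 5), 350L), mk_day(c(3, 4), 350L),
    mk_day(c(3, 7), 450L), mk_day(c(2, 6), 450L)
  )))
  res2 <- day_sd_by_state_anova(s2)
  sds <- c(sd(c(2, 4)), sd(c(1, 5)), sd(c(3, 4)))
  sds2 <- c(sd(c(3, 7)), sd(c(2, 6)))
  tt <- t.test(sds, sds2, var.equal = TRUE)
  expect_equal(res2$F[1], unname(tt$statistic)^2)
  expect_equal(res2$p_value[1], tt$p.value)
})

test_that("day-sd ANOVA detects state-dependent innovation noise", {
  tr <- uniform_truth()
  for (st in esm_states()) names(tr$sigma[[st]]) <- esm_symptoms()
  tr$sigma$full_relapse <- tr$sigma$full_relapse * 2
  plan <- data.frame(state = "full_relapse", start_day = 101L,
                     duration_days = 100L)
  cfg <- test_config(n_monitored_days = 200, state_plan = plan,
                     completion_prob = 0.8,
                     A = tr$A, c = tr$c, sigma = tr$sigma, seed = 31)
  res <- day_sd_by_state_anova(simulate_series(cfg)$series)
  expect_true(all(res$p_value < 0.05))
})

test_that("beeps-per-day ANOVA reports per-state counts and detects completion shifts", {
  plan <- data.frame(state = "full_relapse", start_day = 101L,
                     duration_days = 100L)
  cfg <- test_config(n_monitored_days = 200, state_plan = plan,
                     completion_prob = c(stable = 0.3,
                                         impending_relapse = 0.3,
                                         full_relapse = 0.7),
                     seed = 8)
  res <- beeps_per_day_anova(simulate_series(cfg)$series)
  expect_lt(res$p_value, 0.001)
  per <- res$per_state
  expect_equal(per$n_days[per$state == "stable"], 100L)
  expect_lt(per$mean[per$state == "stable"], per$mean[per$state == "full_relapse"])

  single <- derive_states(make_series(list(list(answered = c(1, 1)))))
  expect_error(beeps_per_day_anova(single), "two states")
})

test_that("beeps-per-day ANOVA is type-I calibrated under equal completion", {
  plan <- data.frame(state = c("impending_relapse", "full_relapse"),
                     start_day = c(35L, 70L), duration_days = c(30L, 30L))
  reps <- 400
  pvals <- vapply(seq_len(reps), function(i) {
    cfg <- test_config(n_monitored_days = 100, state_plan = plan, seed = 5000 + i)
    beeps_per_day_anova(simulate_series(cfg)$series)$p_value
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.03)
  expect_lt(mean(pvals < 0.05), 0.07)
})

test_that("completion stats reproduce the answered-fraction arithmetic", {
  s <- make_series(list(
    list(answered = c(1, 1, 0, 0)), list(answered = c(1, 0, 0, 0))
  ))
  cs <- completion_stats(s)
  expect_equal(cs$n_answered, 3L)
  expect_equal(cs$n_scheduled, 8L)
  expect_equal(cs$fraction, 3 / 8)
  expect_equal(cs$per_day_mean, 1.5)
  expect_equal(c(cs$per_day_min, cs$per_day_max), c(1L, 2L))

  all_in <- make_series(list(list(answered = rep(1, 5))))
  expect_equal(completion_stats(all_in)$fraction, 1)
})
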