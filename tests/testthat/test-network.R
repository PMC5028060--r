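# Hand-built design rows: lagged ratings drawn freely, outcomes set by a
# known linear rule, calendar_day varying.
make_design_rows <- function(n = 40, seed = 2) {
  set.seed(seed)
  syms <- esm_symptoms()
  d <- data.frame(calendar_day = seq_len(n),
                  state = factor("stable", levels = esm_states()))
  for (s in syms) {
    d[[s]] <- NA_real_
    d[[paste0("lag_", s)]] <- sample(1:7, n, replace = TRUE)
  }
  d
}

test_that("noise-free linear data is recovered exactly", {
  d <- make_design_rows()
  d$down <- 1 + 0.5 * d$lag_down
  f <- suppressWarnings(fit_lagged_regression(d, "down"))  # perfect fit
  expect_equal(unname(f$coef["down"]), 0.5, tolerance = 1e-10)
  expect_equal(max(abs(f$coef[setdiff(esm_symptoms(), "down")])), 0,
               tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$time_coef, 0, tolerance = 1e-10)
  expect_equal(f$n, 40L)
})

test_that("a constant outcome yields zero slopes and an undefined R^2", {
  d <- make_design_rows()
  d$down <- 4
  f <- fit_lagged_regression(d, "down")
  expect_equal(max(abs(f$coef)), 0, tolerance = 1e-10)
  expect_true(is.na(f$r_squared))
})

test_that("degenerate designs fail loudly", {
  d <- make_design_rows()
  d$down <- 2 + 0.1 * d$lag_paranoia
  expect_error(fit_lagged_regression(d[1:6, ], "down"), "parameters")
  d2 <- d; d2$lag_relaxed <- 4
  expect_error(fit_lagged_regression(d2, "down"), "lag_relaxed")
  d3 <- d; d3$lag_relaxed <- d3$lag_down
  expect_error(fit_lagged_regression(d3, "down"), "rank-deficient")
})

test_that("design rows require all five lags; outcomes are dropped per model", {
  s <- derive_states(make_series(list(
    list(answered = rep(1, 6),
         down = c(2, 3, 4, 2, 5, 3), relaxed = c(4, 3, NA, 4, 5, 2))
  )))
  pairs <- build_lag_pairs(s)
  rows <- build_design(pairs)
  # the pair whose lag beep (beep 3) misses 'relaxed' is excluded
  expect_equal(nrow(rows), nrow(pairs) - 1L)
  # a missing current 'relaxed' only affects the 'relaxed' model
  expect_equal(sum(is.na(rows$relaxed)), 1L)
  expect_equal(sum(is.na(rows$down)), 0L)
})

test_that("state filtering restricts the design to that state's pairs", {
  series <- simulate_series(test_config(seed = 17))$series
  pairs <- build_lag_pairs(series)
  rows <- build_design(pairs, "full_relapse")
  expect_true(all(rows$state == "full_relapse"))
  lag_cols <- paste0("lag_", esm_symptoms())
  brute <- pairs[pairs$state == "full_relapse" &
                   rowSums(is.na(pairs[lag_cols])) == 0, ]
  expect_equal(nrow(rows), nrow(brute))
  expect_equal(nrow(build_design(pairs)),
               sum(rowSums(is.na(pairs[lag_cols])) == 0))
})

test_that("estimates are deterministic and invariant to row order", {
  series <- simulate_series(test_config(n_monitored_days = 80, seed = 23))$series
  n1 <- estimate_network(series, "stable")
  n2 <- estimate_network(series, "stable")
  expect_identical(n1$W, n2$W)

  pairs <- build_lag_pairs(series)
  rows <- build_design(pairs, "stable")
  set.seed(1)
  shuffled <- rows[sample(nrow(rows)), ]
  f1 <- fit_lagged_regression(rows, "paranoia")
  f2 <- fit_lagged_regression(shuffled, "paranoia")
  expect_equal(f1$coef, f2$coef)
})

test_that("the network assembles per-outcome fits with the j-to-i orientation", {
  series <- simulate_series(test_config(seed = 29))$series
  net <- estimate_network(series, "stable")
  expect_s3_class(net, "symptom_network")
  expect_equal(dim(net$W), c(5L, 5L))
  expect_true(all(is.finite(net$W)))
  f <- fit_lagged_regression(build_design(build_lag_pairs(series), "stable"),
                             "paranoia")
  expect_equal(net$W["paranoia", ], f$coef)  # row = target outcome
  expect_equal(unname(net$n["paranoia"]), as.numeric(f$n))
})

test_that("pooled-state networks use all complete pairs", {
  series <- simulate_series(test_config(n_monitored_days = 80, seed = 41))$series
  net <- estimate_network(series)
  expect_equal(net$state, "all")
  rows <- build_design(build_lag_pairs(series))
  expect_equal(unname(net$n["down"]), sum(!is.na(rows$down)))
})

test_that("a perfect monotone lagged dependence gives Spearman partial +/- 1", {
  set.seed(6)
  days <- lapply(1:30, function(d) {
    par <- sample(1:7, 2, replace = TRUE)
    list(answered = c(1, 1), paranoia = par,
         down = c(sample(1:7, 1), par[1]),  # down(t) copies paranoia(t-1)
         loss_of_control = sample(1:7, 2, replace = TRUE),
         hearing_voices = sample(1:7, 2, replace = TRUE),
         relaxed = sample(1:7, 2, replace = TRUE))
  })
  s <- derive_states(make_series(days))
  net <- spearman_partial_network(s, "stable")
  expect_equal(unname(net$W["down", "paranoia"]), 1, tolerance = 1e-8)
})

test_that("the Spearman network is invariant to monotone transforms", {
  series <- simulate_series(test_config(n_monitored_days = 80, seed = 37))$series
  net <- spearman_partial_network(series, "stable")
  warped <- as.data.frame(series)
  warped$paranoia <- warped$paranoia^3  # strictly increasing on 1..7
  warped <- derive_states(esm_series(warped, validate = FALSE))
  net_w <- spearman_partial_network(warped, "stable")
  expect_equal(net_w$W, net$W, tolerance = 1e-12)
  expect_equal(net_w$p, net$p, tolerance = 1e-12)
})

test_that("zero-variance columns are rejected by the Spearman method", {
  s <- derive_states(make_series(list(
    list(answered = rep(1, 10), down = rep(3L, 10))
  )))
  expect_error(spearman_partial_network(s, "stable"), "zero variance")
})

test_that("network JSON round-trips and GraphML carries signed weights", {
  series <- simulate_series(test_config(n_monitored_days = 80, seed = 43))$series
  net <- estimate_network(series, "stable")
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$W, net$W)
  expect_equal(back$p, net$p)
  expect_equal(back$state, "stable")

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  i <- which(el[, 1] == 3 & el[, 2] == 1)  # paranoia -> down
  expect_equal(w[i], unname(net$W["down", "paranoia"]))
})
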