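#' Write a symptom network to JSON
#'
#' Stores the symptom order, method, state, the 5x5 weight matrix
#' row-major, and (for the regression method) intercepts, time
#' coefficients, standard errors and p-values, plus the per-outcome row
#' counts.
#'
#' @param network A `symptom_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  out <- list(symptoms = network$symptoms, method = network$method,
              state = network$state,
              W = .mat_cols(network$W), n = network$n)
  for (f in c("intercepts", "time_coef", "r_squared")) {
    if (!is.null(network[[f]])) out[[f]] <- network[[f]]
  }
  for (f in c("se", "p")) {
    if (!is.null(network[[f]])) out[[f]] <- .mat_cols(network[[f]])
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

# column-major data frame without row names (which jsonlite would emit as
# a spurious "_row" column)
.mat_cols <- function(m) {
  d <- as.data.frame(m)
  rownames(d) <- NULL
  d
}

#' Read a symptom network from JSON
#'
#' @param path Path written by [write_network_json()].
#' @return A `symptom_network`.
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  syms <- x$symptoms
  net <- list(method = x$method, state = x$state, symptoms = syms,
              W = .json_matrix(x$W, syms))
  if (!is.null(x$n)) net$n <- unlist(x$n)
  for (f in c("intercepts", "time_coef", "r_squared")) {
    if (!is.null(x[[f]])) net[[f]] <- unlist(x[[f]])
  }
  for (f in c("se", "p")) {
    if (!is.null(x[[f]])) net[[f]] <- .json_matrix(x[[f]], syms)
  }
  structure(net, class = "symptom_network")
}

.json_matrix <- function(cols, syms) {
  m <- as.matrix(as.data.frame(cols))
  dimnames(m) <- list(syms, syms)
  m
}

#' Export a symptom network as GraphML
#'
#' Signed weights are kept in the `weight` edge attribute (for plotting
#' tools); exact-zero coefficients are omitted as absent edges.
#'
#' @param network A `symptom_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  W <- network$W
  g <- igraph::graph_from_adjacency_matrix(t(W), mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  igraph::V(g)$label <- unname(esm_symptom_labels()[network$symptoms])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the full ESM network analysis pipeline
#'
#' simulate (or accept) a beep-level series, derive relapse states,
#' summarize completion and episodes, build the per-state descriptive
#' table and contrasts, estimate the symptom network per state and
#' method, and compute centrality tables. States with too few complete
#' lag pairs are marked not estimable without aborting the remaining
#' states. The whole run is deterministic given the config (and its
#' seed).
#'
#' @param input A [synthetic_config()] (the series is generated), an
#'   [esm_series()], or a path to an ESM CSV file.
#' @param states States to fit (default all three).
#' @param methods Network methods (default regression and Spearman
#'   partial).
#' @param dose_state_map Dose-to-state map for state derivation.
#' @param detrend Include the calendar-day covariate in regression fits.
#' @return A `run_report` list: `series`, `truth` (generator runs only),
#'   `completion`, `episodes`, `state_summary`, `contrasts`, `anova`
#'   (beeps/day), `networks` and `centrality` (nested by method then
#'   state; failed states carry an `error` string), `version`.
#' @export
run_pipeline <- function(input, states = esm_states(),
                         methods = c("regression", "spearman_partial"),
                         dose_state_map = default_dose_state_map(),
                         detrend = TRUE) {
  truth <- NULL
  if (inherits(input, "synthetic_config")) {
    sim <- simulate_series(input)
    series <- sim$series
    truth <- sim$truth
  } else if (inherits(input, "esm_series")) {
    series <- input
  } else if (is.character(input) && length(input) == 1) {
    series <- read_esm_csv(input)
  } else {
    stop("run_pipeline: input must be a synthetic_config, esm_series or ",
         "CSV path", call. = FALSE)
  }
  if (!"state" %in% names(series)) {
    series <- derive_states(series, dose_state_map)
  }

  contrasts <- do.call(rbind, lapply(esm_symptoms(), function(s) {
    do.call(rbind, lapply(setdiff(states, "stable"), function(st) {
      tryCatch(compare_states(series, s, "stable", st),
               error = function(e) NULL)
    }))
  }))

  networks <- centrality <- list()
  for (m in methods) {
    networks[[m]] <- centrality[[m]] <- list()
    for (st in states) {
      net <- tryCatch(estimate_network(series, st, method = m,
                                       detrend = detrend),
                      error = function(e) list(error = conditionMessage(e)))
      networks[[m]][[st]] <- net
      centrality[[m]][[st]] <-
        if (inherits(net, "symptom_network")) centrality_table(net) else
          list(error = "network not estimable")
    }
  }

  structure(list(
    series = series, truth = truth,
    completion = completion_stats(series),
    episodes = segment_episodes(series),
    state_summary = state_summary(series),
    contrasts = contrasts,
    anova = tryCatch(beeps_per_day_anova(series),
                     error = function(e) list(error = conditionMessage(e))),
    networks = networks, centrality = centrality,
    version = as.character(utils::packageVersion("esmnet"))
  ), class = "run_report")
}

#' Export a run report to files
#'
#' Writes the series CSV, completion/episode/summary/contrast tables
#' (CSV), each estimable network as JSON and GraphML, each centrality
#' table as CSV, and a manifest (JSON) listing every file with its MD5
#' checksum — identical configs and seeds reproduce identical manifests.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest as a data frame.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put_csv <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE, na = "")
    written <<- c(written, p)
  }
  write_esm_csv(report$series, file.path(dir, "series.csv"))
  written <- c(written, file.path(dir, "series.csv"))
  if (!is.null(report$truth)) {
    write_ground_truth(report$truth, file.path(dir, "ground_truth.json"))
    written <- c(written, file.path(dir, "ground_truth.json"))
  }
  put_csv(as.data.frame(report$completion), "completion.csv")
  put_csv(report$episodes$episodes, "episodes.csv")
  put_csv(report$episodes$summary, "episode_summary.csv")
  put_csv(report$state_summary, "state_summary.csv")
  if (!is.null(report$contrasts)) put_csv(report$contrasts, "contrasts.csv")
  put_csv(day_level_series(report$series), "day_series.csv")
  for (m in names(report$networks)) {
    for (st in names(report$networks[[m]])) {
      net <- report$networks[[m]][[st]]
      if (!inherits(net, "symptom_network")) next
      base <- paste0("network_", m, "_", st)
      write_network_json(net, file.path(dir, paste0(base, ".json")))
      write_graphml(net, file.path(dir, paste0(base, ".graphml")))
      written <- c(written, file.path(dir, paste0(base, ".json")),
                   file.path(dir, paste0(base, ".graphml")))
      ct <- report$centrality[[m]][[st]]
      if (is.data.frame(ct)) put_csv(ct, paste0("centrality_", m, "_", st, ".csv"))
    }
  }
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  jsonlite::write_json(list(version = report$version, files = manifest),
                       file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(manifest)
}
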