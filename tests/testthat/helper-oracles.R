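# Exhaustive simple-path enumeration oracle for shortest-path centrality.
# Independent of the Dijkstra/Brandes implementation: enumerates every
# simple path between each ordered node pair, takes the minimal total
# distance, counts minimal paths (relative tolerance), and accumulates
# fractional betweenness over interior nodes.

oracle_centrality <- function(D, tol = 1e-9) {
  n <- nrow(D)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1  # Brandes convention: one empty path from a node to itself
  btw <- rep(0, n)

  enumerate <- function(s, t) {
    paths <- list()
    walk <- function(path, len) {
      u <- path[length(path)]
      if (u == t) {
        paths[[length(paths) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (v in seq_len(n)) {
        if (v %in% path || is.infinite(D[u, v])) next
        walk(c(path, v), len + D[u, v])
      }
    }
    walk(s, 0)
    paths
  }

  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- enumerate(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, function(p) p$len, numeric(1))
      dmin <- min(lens)
      minimal <- paths[lens <= dmin + tol * max(1, dmin)]
      dist[s, t] <- dmin
      sigma[s, t] <- length(minimal)
      for (p in minimal) {
        interior <- setdiff(p$path, c(s, t))
        for (v in interior) btw[v] <- btw[v] + 1 / length(minimal)
      }
    }
  }
  totals <- rowSums(dist)
  clo <- ifelse(is.finite(totals) & totals > 0, 1 / totals, 0)
  list(dist = dist, sigma = sigma, betweenness = btw, closeness = clo)
}

# Random weighted digraph: weights U(-1, 1), a fraction zeroed (absent).
random_W <- function(n = 5, zero_frac = 0.3) {
  W <- matrix(stats::runif(n * n, -1, 1), n, n)
  W[sample(n * n, round(zero_frac * n * n))] <- 0
  dimnames(W) <- list(paste0("v", 1:n), paste0("v", 1:n))
  W
}
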