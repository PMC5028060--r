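# Centrality indices for weighted directed symptom networks.
#
# Edge weights may be negative (regression coefficients); all strength and
# distance computations use |w|, the convention of the network tooling the
# indices come from. Self-loops count in strengths (twice in node strength)
# but never participate in paths. Distance of an edge is 1/|w|; an exactly
# zero coefficient means "no edge".

.as_W <- function(network) {
  if (inherits(network, "symptom_network")) network$W else as.matrix(network)
}

#' Inward, outward and node strength
#'
#' Outward strength of a node is the sum of the absolute weights of its
#' outgoing edges (including the self-loop); inward strength the sum over
#' incoming edges (again including the self-loop); node strength is their
#' sum, so the self-loop is counted twice. With `W[i, j]` the weight of
#' edge `j -> i`, inward is the absolute row sum and outward the absolute
#' column sum.
#'
#' @param network A `symptom_network` or a weighted adjacency matrix with
#'   `W[i, j]` = weight of edge `j -> i`.
#' @return Data frame with `node`, `inward_strength`, `outward_strength`,
#'   `node_strength`.
#' @export
strengths <- function(network) {
  W <- .as_W(network)
  nodes <- rownames(W) %||% paste0("v", seq_len(nrow(W)))
  inward <- rowSums(abs(W))
  outward <- colSums(abs(W))
  data.frame(node = nodes, inward_strength = unname(inward),
             outward_strength = unname(outward),
             node_strength = unname(inward + outward))
}

#' Distance graph of a weighted network
#'
#' Converts edge weights to travel costs: `d[s, t] = 1 / |W[t, s]|` for
#' each nonzero edge `s -> t` (after optional thresholding), `Inf`
#' otherwise; self-loops are excluded. Stronger connections are shorter
#' distances.
#'
#' @inheritParams strengths
#' @param threshold Absolute weights at or below this value are treated
#'   as absent edges (default 0: only exact zeros are absent).
#' @return Square matrix of positive distances, `Inf` for absent edges,
#'   `0` on the diagonal.
#' @export
distance_graph <- function(network, threshold = 0) {
  W <- .as_W(network)
  aw <- abs(t(W))  # aw[s, t] = |weight of s -> t|
  D <- ifelse(aw > threshold, 1 / aw, Inf)
  diag(D) <- 0
  dimnames(D) <- list(colnames(W), colnames(W))
  D
}

# Dijkstra from one source with minimal-path counting (Brandes bookkeeping).
# Ties in path length are detected with a relative tolerance.
.dijkstra <- function(D, s, tol = 1e-12) {
  n <- nrow(D)
  dist <- rep(Inf, n); dist[s] <- 0
  sigma <- rep(0, n); sigma[s] <- 1
  preds <- vector("list", n)
  visited <- rep(FALSE, n)
  order_visited <- integer(0)
  repeat {
    u <- which(!visited & dist < Inf)
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    visited[u] <- TRUE
    order_visited <- c(order_visited, u)
    for (v in seq_len(n)) {
      if (v == u || is.infinite(D[u, v])) next
      alt <- dist[u] + D[u, v]
      eps <- tol * max(1, abs(alt), if (is.finite(dist[v])) abs(dist[v]) else 0)
      if (alt < dist[v] - eps) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (is.finite(dist[v]) && abs(alt - dist[v]) <= eps && !visited[v]) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_visited)
}

#' All-pairs shortest distances and minimal-path counts
#'
#' Dijkstra from every source on the distance graph. Negative distances
#' are rejected (they cannot arise from the `1/|w|` transform and
#' indicate corrupted input).
#'
#' @param D Distance matrix from [distance_graph()].
#' @param tol Relative tolerance for detecting equal-length paths.
#' @return List with `dist` (matrix, `Inf` = unreachable) and `sigma`
#'   (matrix of minimal-path counts).
#' @export
shortest_paths <- function(D, tol = 1e-12) {
  if (any(D < 0)) stop("shortest_paths: negative distance", call. = FALSE)
  n <- nrow(D)
  dist <- sigma <- matrix(NA_real_, n, n, dimnames = dimnames(D))
  for (s in seq_len(n)) {
    r <- .dijkstra(D, s, tol)
    dist[s, ] <- r$dist
    sigma[s, ] <- r$sigma
  }
  list(dist = dist, sigma = sigma)
}

#' Closeness centrality
#'
#' The inverse of the summed shortest outgoing distances from a node to
#' all other nodes, `1 / sum_u d(v, u)`. If any node is unreachable the
#' sum is infinite and the closeness is 0 (a node with no outgoing edges
#' therefore has closeness 0). Scaling all weights by `c > 0` scales all
#' closeness values by `c`.
#'
#' @inheritParams strengths
#' @param threshold Passed to [distance_graph()].
#' @return Named numeric vector of closeness values.
#' @export
closeness <- function(network, threshold = 0) {
  D <- distance_graph(network, threshold)
  sp <- shortest_paths(D)
  totals <- rowSums(sp$dist) # diagonal contributes 0
  ifelse(is.finite(totals) & totals > 0, 1 / totals,
         ifelse(totals == 0, Inf, 0))
}

#' Betweenness centrality
#'
#' Fractional (Brandes) betweenness on the distance graph: for each
#' ordered pair of distinct other nodes `(s, t)`, the node `v` receives
#' the fraction of minimal-distance `s -> t` paths that pass through it;
#' endpoints are excluded and self-loops ignored. With continuous
#' estimated weights exact ties have measure zero, so values are integers
#' in practice.
#'
#' @inheritParams closeness
#' @param tol Relative tolerance for equal-length path detection.
#' @return Named numeric vector of betweenness values.
#' @export
betweenness <- function(network, threshold = 0, tol = 1e-12) {
  D <- distance_graph(network, threshold)
  n <- nrow(D)
  bc <- rep(0, n)
  for (s in seq_len(n)) {
    r <- .dijkstra(D, s, tol)
    delta <- rep(0, n)
    for (w in rev(r$order)) {
      for (p in r$preds[[w]]) {
        delta[p] <- delta[p] + r$sigma[p] / r$sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc, rownames(D))
}

#' Centrality table for a symptom network
#'
#' All five indices — betweenness, closeness, inward strength, outward
#' strength, node strength — per symptom, in canonical order.
#'
#' @inheritParams closeness
#' @return Data frame with columns `symptom`, `betweenness`, `closeness`,
#'   `inward_strength`, `outward_strength`, `node_strength`.
#' @export
centrality_table <- function(network, threshold = 0) {
  W <- .as_W(network)
  st <- strengths(W)
  data.frame(symptom = st$node,
             betweenness = unname(betweenness(W, threshold)),
             closeness = unname(closeness(W, threshold)),
             inward_strength = st$inward_strength,
             outward_strength = st$outward_strength,
             node_strength = st$node_strength)
}
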