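# Whole-graph topology on non-negatively thresholded connectivity
# matrices. Weighted shortest paths use edge lengths 1/weight (the usual
# transform for correlation-weighted graphs); zero-weight entries are
# non-edges. igraph's C routines provide paths, betweenness and community
# detection; the resilience index composes them.

#' Threshold a connectivity matrix to non-negative weights
#'
#' Sets negative entries to zero and leaves positive ones untouched. The
#' diagonal is zeroed (self-connections are not edges).
#'
#' @param W Symmetric numeric matrix.
#' @return Object of class `thresholded_graph`: list with `weights`
#'   (symmetric non-negative, zero diagonal), `n_nodes` and `n_total`
#'   (= n(n-1)/2, the number of possible edges).
#' @export
threshold_nonnegative <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-8)
    stop("W must be symmetric")
  diag(W) <- 0
  W[W < 0] <- 0
  n <- nrow(W)
  structure(list(weights = W, n_nodes = n, n_total = n * (n - 1) / 2),
            class = "thresholded_graph")
}

as_tgraph <- function(G) {
  if (inherits(G, "thresholded_graph")) G else threshold_nonnegative(G)
}

tgraph_igraph <- function(G) {
  igraph::graph_from_adjacency_matrix(G$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the reciprocal weighted shortest-path
#' distance, with edge lengths 1/weight; unreachable pairs contribute 0.
#' Equals 1 for a complete unit-weight graph and 0 for an edgeless one.
#'
#' @param G A `thresholded_graph` (or symmetric matrix, thresholded
#'   internally).
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(G) {
  G <- as_tgraph(G)
  n <- G$n_nodes
  if (n < 2) return(0)
  g <- tgraph_igraph(G)
  if (igraph::ecount(g) == 0) return(0)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Deterministic weighted modularity
#'
#' Maximizes the weighted Newman-Girvan modularity Q at resolution 1 with
#' a deterministic procedure: the exact GLPK integer-program optimum for
#' graphs up to `exact_max` nodes, and the Newman leading-eigenvector
#' method (deterministic spectral bipartitioning) above that size.
#' Repeated calls on the same graph return identical results.
#'
#' @param G A `thresholded_graph` or symmetric matrix.
#' @param exact_max Largest node count for which the exact optimum is
#'   computed (default 16).
#' @return List with `Q` (modularity) and `partition` (integer community
#'   membership vector).
#' @export
modularity_graph <- function(G, exact_max = 16) {
  G <- as_tgraph(G)
  g <- tgraph_igraph(G)
  if (igraph::ecount(g) == 0)
    stop("undefined modularity: graph has no edges")
  cl <- if (G$n_nodes <= exact_max) {
    igraph::cluster_optimal(g, weights = igraph::E(g)$weight)
  } else {
    igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight)
  }
  list(Q = igraph::modularity(g, igraph::membership(cl),
                              weights = igraph::E(g)$weight),
       partition = as.integer(igraph::membership(cl)))
}

#' Weighted edge betweenness
#'
#' Brandes' edge betweenness on edge lengths 1/weight: for every
#' unordered node pair (counted once), shortest-path multiplicity is
#' shared fractionally among equal-length paths. Unnormalized. With
#' `binary = TRUE` the thresholded graph is binarized first (every
#' surviving edge has unit length).
#'
#' @param G A `thresholded_graph` or symmetric matrix.
#' @param binary Use unit edge lengths instead of 1/weight.
#' @return Data frame with columns `from`, `to` (node indices,
#'   `from < to`), `weight` and `betweenness`.
#' @export
edge_betweenness_graph <- function(G, binary = FALSE) {
  G <- as_tgraph(G)
  g <- tgraph_igraph(G)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0)
    return(data.frame(from = integer(0), to = integer(0),
                      weight = numeric(0), betweenness = numeric(0)))
  lens <- if (binary) rep(1, igraph::ecount(g)) else
    1 / igraph::E(g)$weight
  eb <- igraph::edge_betweenness(g, weights = lens)
  data.frame(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
             weight = igraph::E(g)$weight, betweenness = eb)
}

#' Topological resilience under high-betweenness edge removal
#'
#' Simulates network degradation: computes edge betweenness once on the
#' original graph, removes every edge whose betweenness exceeds 1
#' (leaving only edges that no shortest path, or exactly one, passes
#' through), and quantifies the efficiency loss per removed edge scaled
#' by the number of possible edges:
#' `G_Res = (E_100 - E_0) / N_removed * N_total`. If no edge qualifies
#' for removal the index is 0 by convention. The index is never positive.
#'
#' @param G A `thresholded_graph` or symmetric matrix.
#' @param binary Compute the betweenness used for removal on the
#'   binarized graph (default weighted).
#' @return List of class `resilience_result`: `E_0`, `E_100`,
#'   `N_removed`, `N_total`, `G_Res`.
#' @export
resilience <- function(G, binary = FALSE) {
  G <- as_tgraph(G)
  E0 <- global_efficiency(G)
  eb <- edge_betweenness_graph(G, binary = binary)
  drop <- eb$betweenness > 1 + 1e-9
  n_removed <- sum(drop)
  if (n_removed == 0) {
    return(structure(list(E_0 = E0, E_100 = E0, N_removed = 0L,
                          N_total = G$n_total, G_Res = 0),
                     class = "resilience_result"))
  }
  W <- G$weights
  W[cbind(eb$from[drop], eb$to[drop])] <- 0
  W[cbind(eb$to[drop], eb$from[drop])] <- 0
  E100 <- global_efficiency(threshold_nonnegative(W))
  structure(list(E_0 = E0, E_100 = E100, N_removed = n_removed,
                 N_total = G$n_total,
                 G_Res = (E100 - E0) / n_removed * G$n_total),
            class = "resilience_result")
}

#' Per-frame topological index series
#'
#' Thresholds every frame's correlation matrix and computes global
#' efficiency, deterministic modularity and resilience. Frames on which
#' an index is undefined (e.g. modularity of an edgeless frame) are
#' recorded as `NA` with a diagnostic message collected in the
#' `failures` attribute.
#'
#' @param R A [dcc_series] or `p x p x T` array.
#' @param exact_max Passed to [modularity_graph()].
#' @return Data frame with columns `frame`, `G_Eff`, `G_Mod`, `G_Res`.
#' @export
topology_series <- function(R, exact_max = 16) {
  arr <- if (inherits(R, "dcc_series")) R$R else R
  if (length(dim(arr)) != 3 || dim(arr)[1] != dim(arr)[2])
    stop("R must be a p x p x T array")
  Tn <- dim(arr)[3]
  out <- data.frame(frame = seq_len(Tn), G_Eff = NA_real_,
                    G_Mod = NA_real_, G_Res = NA_real_)
  failures <- character(0)
  for (t in seq_len(Tn)) {
    G <- threshold_nonnegative(arr[, , t])
    out$G_Eff[t] <- global_efficiency(G)
    m <- tryCatch(modularity_graph(G, exact_max = exact_max),
                  error = function(e) e)
    if (inherits(m, "error")) {
      failures <- c(failures, paste0("frame ", t, ": ", conditionMessage(m)))
    } else {
      out$G_Mod[t] <- m$Q
    }
    out$G_Res[t] <- resilience(G)$G_Res
  }
  attr(out, "failures") <- failures
  out
}
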