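# Independent brute-force oracles used to cross-check the graph metrics,
# the task-weighted statistic and the FDR step-up. These deliberately do
# not share code paths with the implementation.

# All-pairs shortest paths by Floyd-Warshall on edge lengths 1/weight.
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

oracle_efficiency <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- oracle_distances(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Edge betweenness by exhaustive enumeration of all simple paths per node
# pair (pruned at the best known length); equal-length shortest paths
# share credit equally.
oracle_betweenness <- function(W, tol = 1e-10) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  eb <- matrix(0, n, n)
  for (s in seq_len(n - 1)) for (tt in (s + 1):n) {
    best <- Inf
    paths <- list()
    dfs <- function(v, visited, len, path) {
      if (len > best + tol) return()
      if (v == tt) {
        if (len < best - tol) {
          best <<- len
          paths <<- list(path)
        } else {
          paths[[length(paths) + 1]] <<- path
        }
        return()
      }
      for (u in which(is.finite(L[v, ]))) {
        if (!visited[u]) {
          visited[u] <- TRUE
          dfs(u, visited, len + L[v, u], c(path, u))
          visited[u] <- FALSE
        }
      }
    }
    vis <- rep(FALSE, n)
    vis[s] <- TRUE
    dfs(s, vis, 0, s)
    if (length(paths)) {
      share <- 1 / length(paths)
      for (pth in paths) {
        for (k in seq_len(length(pth) - 1)) {
          i <- pth[k]; j <- pth[k + 1]
          eb[i, j] <- eb[i, j] + share
          eb[j, i] <- eb[j, i] + share
        }
      }
    }
  }
  eb
}

# Maximum weighted Newman-Girvan modularity by exhaustive search over all
# set partitions (restricted-growth-string enumeration); n <= 9 or so.
oracle_modularity <- function(W) {
  n <- nrow(W)
  two_m <- sum(W)
  k <- rowSums(W)
  B <- W - outer(k, k) / two_m
  best <- -Inf
  rg <- integer(n)
  rec <- function(i, maxg) {
    if (i > n) {
      S <- outer(rg, rg, `==`)
      q <- sum(B[S]) / two_m
      if (q > best) best <<- q
      return()
    }
    for (g in seq_len(maxg + 1)) {
      rg[i] <<- g
      rec(i + 1, max(maxg, g))
    }
  }
  rec(1L, 0L)
  best
}

# Direct evaluation of the task-modulated statistics from their
# definition: per-trial sample SD (divisor T1 - 1) and mean of the
# weighted trace, averaged over trials.
oracle_dsd <- function(trace, h, frame_sets) {
  per_trial <- sapply(frame_sets, function(fr) {
    d <- trace[fr] * h[fr]
    e_d <- sum(d) / length(d)
    sqrt(sum((d - e_d)^2) / (length(d) - 1))
  })
  sum(per_trial) / length(per_trial)
}

oracle_dmean <- function(trace, h, frame_sets) {
  mean(sapply(frame_sets, function(fr) mean(trace[fr] * h[fr])))
}

# Hand-rolled BH step-up q-values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Random symmetric non-negative weighted graph on n nodes.
random_graph <- function(n, p_edge = 0.6, negatives = FALSE) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  vals <- ifelse(stats::runif(sum(up)) < p_edge,
                 stats::runif(sum(up), 0.2, 1.5), 0)
  if (negatives) {
    flip <- stats::runif(length(vals)) < 0.3
    vals[flip] <- -vals[flip]
  }
  W[up] <- vals
  W <- W + t(W)
  diag(W) <- 0
  W
}

# Manually built trial window (bypasses the design machinery).
make_window <- function(frames, condition = "toy", index = 1L) {
  structure(list(condition = condition, trial_index = index,
                 frames = frames, T1 = length(frames)),
            class = "trial_window")
}
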