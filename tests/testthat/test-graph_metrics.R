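path_graph <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W
}

test_that("thresholding zeroes negatives symmetrically and fixes N_total", {
  W <- matrix(c(0, 0.5, -0.3, 0.5, 0, 0.2, -0.3, 0.2, 0), 3)
  G <- threshold_nonnegative(W)
  expect_equal(G$weights[1, 3], 0)
  expect_equal(G$weights[3, 1], 0)
  expect_equal(G$weights[1, 2], 0.5)
  expect_equal(G$n_total, 3)
  expect_equal(min(G$weights), 0)
  Wpos <- abs(W)
  expect_equal(threshold_nonnegative(Wpos)$weights, Wpos)
  expect_error(threshold_nonnegative(matrix(1:4, 2)), "symmetric")
  expect_equal(threshold_nonnegative(matrix(0, 347, 347))$n_total, 60031)
})

test_that("global efficiency: complete, path and edgeless graphs", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(global_efficiency(threshold_nonnegative(K4)), 1)
  expect_equal(global_efficiency(threshold_nonnegative(path_graph())), 5 / 6)
  expect_equal(global_efficiency(threshold_nonnegative(matrix(0, 4, 4))), 0)
})

test_that("modularity: clique, two cliques, determinism, edgeless error", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  m <- modularity_graph(threshold_nonnegative(K4))
  expect_equal(m$Q, 0, tolerance = 1e-12)
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- K4
  W[5:8, 5:8] <- K4
  m2 <- modularity_graph(threshold_nonnegative(W))
  expect_equal(m2$Q, 0.5, tolerance = 1e-12)
  expect_length(unique(m2$partition), 2)
  m2b <- modularity_graph(threshold_nonnegative(W))
  expect_identical(m2, m2b)
  expect_error(modularity_graph(threshold_nonnegative(matrix(0, 3, 3))),
               "no edges")
})

test_that("edge betweenness: single edge, path and star", {
  W1 <- matrix(0, 2, 2); W1[1, 2] <- W1[2, 1] <- 1
  expect_equal(edge_betweenness_graph(threshold_nonnegative(W1))$betweenness, 1)
  ebp <- edge_betweenness_graph(threshold_nonnegative(path_graph()))
  expect_equal(sort(ebp$betweenness), c(2, 2))
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  ebs <- edge_betweenness_graph(threshold_nonnegative(star))
  expect_equal(ebs$betweenness, rep(3, 3))
})

test_that("resilience follows the efficiency-loss-per-removed-edge definition", {
  r <- resilience(threshold_nonnegative(path_graph()))
  expect_equal(r$E_0, 5 / 6)
  expect_equal(r$E_100, 0)
  expect_equal(r$N_removed, 2L)
  expect_equal(r$N_total, 3)
  expect_equal(r$G_Res, -1.25)
  # every edge betweenness <= 1 -> nothing removed, zero by convention
  W1 <- matrix(0, 2, 2); W1[1, 2] <- W1[2, 1] <- 1
  r1 <- resilience(threshold_nonnegative(W1))
  expect_equal(r1$N_removed, 0L)
  expect_equal(r1$G_Res, 0)
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  set.seed(100)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    W <- random_graph(n, negatives = TRUE)
    G <- threshold_nonnegative(W)
    Wp <- G$weights
    expect_equal(global_efficiency(G), oracle_efficiency(Wp),
                 tolerance = 1e-10)
    if (sum(Wp) > 0) {
      expect_equal(modularity_graph(G)$Q, oracle_modularity(Wp),
                   tolerance = 1e-8)
      eb <- edge_betweenness_graph(G)
      ebo <- oracle_betweenness(Wp)
      expect_equal(eb$betweenness, ebo[cbind(eb$from, eb$to)],
                   tolerance = 1e-8)
      # resilience identity recomputed from the oracles
      r <- resilience(G)
      drop <- ebo[cbind(eb$from, eb$to)] > 1 + 1e-9
      W2 <- Wp
      W2[cbind(eb$from[drop], eb$to[drop])] <- 0
      W2[cbind(eb$to[drop], eb$from[drop])] <- 0
      e100 <- oracle_efficiency(W2)
      gres <- if (sum(drop) == 0) 0 else
        (e100 - oracle_efficiency(Wp)) / sum(drop) * G$n_total
      expect_equal(r$G_Res, gres, tolerance = 1e-8)
      expect_lte(r$E_100, r$E_0 + 1e-12)
      expect_lte(r$G_Res, 0)
      expect_gte(modularity_graph(G)$Q, 0 - 1e-12)
    }
  }
})

test_that("efficiency is monotone in single-weight increases", {
  set.seed(101)
  for (rep in 1:10) {
    W <- random_graph(6)
    e0 <- global_efficiency(threshold_nonnegative(W))
    i <- sample(6, 2)
    W2 <- W
    W2[i[1], i[2]] <- W2[i[2], i[1]] <- W[i[1], i[2]] + 0.5
    expect_gte(global_efficiency(threshold_nonnegative(W2)), e0 - 1e-12)
  }
})

test_that("topology series reproduces single-frame metrics per frame", {
  set.seed(102)
  p <- 10
  Tn <- 5
  R <- array(0, c(p, p, Tn))
  for (t in seq_len(Tn)) {
    A <- random_graph(p, negatives = TRUE)
    R[, , t] <- A
  }
  ts <- topology_series(R)
  expect_equal(nrow(ts), Tn)
  for (t in seq_len(Tn)) {
    G <- threshold_nonnegative(R[, , t])
    expect_equal(ts$G_Eff[t], global_efficiency(G))
    expect_equal(ts$G_Mod[t], modularity_graph(G)$Q)
    expect_equal(ts$G_Res[t], resilience(G)$G_Res)
  }
  # constant stack -> constant traces
  Rc <- array(R[, , 1], c(p, p, 3))
  tc <- topology_series(Rc)
  expect_equal(length(unique(tc$G_Eff)), 1)
  expect_equal(length(unique(tc$G_Mod)), 1)
  expect_equal(length(unique(tc$G_Res)), 1)
  # edgeless frames are flagged missing, others computed
  Rz <- Rc
  Rz[, , 2] <- -abs(Rz[, , 2])
  tz <- topology_series(Rz)
  expect_true(is.na(tz$G_Mod[2]))
  expect_false(anyNA(tz$G_Mod[c(1, 3)]))
  expect_length(attr(tz, "failures"), 1)
})
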