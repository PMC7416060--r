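# Simulate a plain GARCH(1,1) series (no correlation structure needed).
sim_garch <- function(T, omega, alpha, beta, seed) {
  set.seed(seed)
  x <- numeric(T)
  h <- omega / (1 - alpha - beta)
  for (t in seq_len(T)) {
    if (t > 1) h <- omega + alpha * x[t - 1]^2 + beta * h
    x[t] <- sqrt(h) * rnorm(1)
  }
  x
}

test_that("GARCH(1,1) estimates are close to truth and beat it in likelihood", {
  for (seed in 1:8) {
    x <- sim_garch(5000, 0.1, 0.1, 0.8, seed)
    f <- fit_garch11(x)
    expect_true(f$converged)
    expect_lt(abs(f$alpha - 0.1), 0.1)
    expect_lt(abs(f$beta - 0.8), 0.15)
    # QML optimality: fitted likelihood at least that of the generator
    expect_gte(f$log_likelihood, garch11_loglik(x, 0.1, 0.1, 0.8) - 1e-6)
  }
})

test_that("GARCH fit rejects degenerate input", {
  expect_error(fit_garch11(rep(1, 200)), "zero-variance")
  expect_error(fit_garch11(rnorm(50)), "too short")
})

test_that("DCC fit on constant-correlation data degenerates gracefully", {
  set.seed(42)
  Sigma <- matrix(0.5, 4, 4) + diag(0.5, 4)
  Z <- matrix(rnorm(2000 * 4), 2000) %*% chol(Sigma)
  f <- fit_dcc(Z)
  expect_lt(f$a, 0.05)
  R <- dcc_correlations(f, Z)
  S <- cor(Z)
  expect_lt(max(abs(R - array(S, dim(R)))), 0.05)
})

test_that("a = b = 0 gives a constant correlation path", {
  set.seed(7)
  Z <- matrix(rnorm(600), 200, 3)
  f0 <- structure(list(a = 0, b = 0, Qbar = cor(Z), log_likelihood = NA,
                       converged = TRUE), class = "dcc_fit")
  R <- dcc_correlations(f0, Z)
  expect_lt(max(abs(sweep(R, c(1, 2), R[, , 1]))), 1e-14)
})

test_that("DCC tracks time-varying correlation better than the static estimate", {
  sim <- simulate_garch_dcc(p = 5, T = 2000, a = 0.05, b = 0.90, seed = 21)
  fit <- dcc_series(sim$X, factorization = "joint")
  err_dcc <- mean(abs(fit$R - sim$R_true))
  S <- cor(scale(sim$X))
  err_static <- mean(abs(array(S, dim(fit$R)) - sim$R_true))
  expect_lt(err_dcc, err_static)
  # consistency: framewise tracking improves with longer series
  sim_s <- simulate_garch_dcc(p = 5, T = 500, a = 0.05, b = 0.90, seed = 22)
  fit_s <- dcc_series(sim_s$X, factorization = "joint")
  sim_l <- simulate_garch_dcc(p = 5, T = 2000, a = 0.05, b = 0.90, seed = 22)
  fit_l <- dcc_series(sim_l$X, factorization = "joint")
  expect_lt(mean(abs(fit_l$R - sim_l$R_true)),
            mean(abs(fit_s$R - sim_s$R_true)))
})

test_that("dcc_series output satisfies the correlation-series contract", {
  set.seed(3)
  X <- matrix(rnorm(200 * 5), 200)
  for (mode in c("joint", "pairwise")) {
    fit <- dcc_series(X, factorization = mode)
    expect_equal(dim(fit$R), c(5, 5, 200)) # no edge loss
    expect_lt(max(abs(fit$R - aperm(fit$R, c(2, 1, 3)))), 1e-12)
    for (t in c(1, 100, 200))
      expect_equal(unname(diag(fit$R[, , t])), rep(1, 5))
    expect_true(all(abs(fit$R) <= 1 + 1e-12))
  }
  # PSD holds by construction for the joint recursion
  fitj <- dcc_series(X, factorization = "joint")
  for (t in c(1, 50, 150))
    expect_gt(min(eigen(fitj$R[, , t], symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
})

test_that("dcc_series rejects malformed input", {
  X <- matrix(rnorm(400), 200, 2)
  X[5, 1] <- NA
  expect_error(dcc_series(X), "missing")
  X2 <- cbind(rnorm(200), 1)
  colnames(X2) <- c("a", "b")
  expect_error(dcc_series(X2), "zero-variance")
  expect_error(dcc_series(matrix(rnorm(90), 30, 3)), "100 frames")
})

test_that("region permutation and positive scaling leave correlations consistent", {
  set.seed(9)
  sim <- simulate_garch_dcc(p = 4, T = 400, a = 0.05, b = 0.9, seed = 9)
  X <- sim$X
  colnames(X) <- paste0("r", 1:4)
  fit <- dcc_series(X)
  perm <- c(3, 1, 4, 2)
  fitp <- dcc_series(X[, perm])
  expect_equal(fitp$R, fit$R[perm, perm, ], tolerance = 1e-10)
  # scale invariance of the two-stage estimator
  Xs <- X
  Xs[, 2] <- X[, 2] * 7.5
  fits <- dcc_series(Xs)
  expect_lt(max(abs(fits$R - fit$R)), 1e-6)
})

test_that("time-mean of dynamic correlations matches the static correlation on stationary data", {
  set.seed(11)
  Sigma <- matrix(0.4, 5, 5) + diag(0.6, 5)
  X <- matrix(rnorm(1500 * 5), 1500) %*% chol(Sigma)
  fit <- dcc_series(X, factorization = "joint")
  expect_lt(max(abs(apply(fit$R, c(1, 2), mean) - cor(scale(X)))), 0.05)
})
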