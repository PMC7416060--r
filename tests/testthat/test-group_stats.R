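# Cheap long-format stat table from given per-measure group means
# (bypasses the estimator; exercises only the inference layer).
fake_stat_tbl <- function(n_per_group, shift = c(), sd = 1,
                          measures = connection_types(), seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  subjects <- sprintf("s%03d", seq_len(n))
  groups <- rep(c("CON", "CAN"), each = n_per_group)
  conds <- names(condition_codes())
  tab <- expand.grid(subject = subjects, measure = measures,
                     condition = conds, stringsAsFactors = FALSE)
  tab$measure_class <- "primary"
  mu <- ifelse(tab$measure %in% names(shift) &
                 groups[match(tab$subject, subjects)] == "CAN",
               shift[tab$measure], 0)
  tab$d_sd <- rnorm(nrow(tab), mu, sd)
  tab$d_mean <- rnorm(nrow(tab))
  cov <- data.frame(subject = subjects, group = groups,
                    age = rnorm(n, 30, 8), mean_fd = abs(rnorm(n, 0.1, 0.03)),
                    craving_prescan = rnorm(n),
                    craving_duringscan = rnorm(n))
  list(tab = tab, cov = cov)
}

test_that("Welch t from summaries reproduces the demographic age contrast", {
  w <- welch_t_from_summary(29.40, 10.15, 90, 29.35, 7.93, 54)
  expect_lt(abs(w$t - 0.032), 0.001)
  expect_lt(abs(w$df - 132.237), 0.1)
  expect_equal(welch_t_from_summary(5, 1, 10, 5, 2, 12)$t, 0)
  # equal variances and n: Welch equals the pooled t
  x <- c(1.2, 2.3, 0.8, 1.9); y <- c(2.2, 3.1, 1.4, 2.8)
  w2 <- welch_t_from_summary(mean(x), sd(x), 4, mean(y), sd(y), 4)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(w2$t, unname(tt$statistic), tolerance = 1e-4)
  expect_error(welch_t_from_summary(1, 0, 10, 2, 0, 10), "sd > 0")
  expect_error(welch_t_from_summary(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("2x2 chi-square reproduces the demographic sex contrast", {
  r <- chi_square_2x2(rbind(c(45, 45), c(31, 23)))
  expect_equal(r$chi2, 0.743, tolerance = 5e-4)
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(20, 20)))$chi2, 0)
  set.seed(2)
  tabm <- matrix(rpois(4, 20) + 1, 2)
  r2 <- chi_square_2x2(tabm)
  cs <- suppressWarnings(chisq.test(tabm, correct = FALSE))
  expect_equal(r2$chi2, unname(cs$statistic))
  expect_equal(r2$p, cs$p.value)
  # invariance under row and column swaps
  expect_equal(chi_square_2x2(tabm[2:1, ])$chi2, r2$chi2)
  expect_equal(chi_square_2x2(tabm[, 2:1])$chi2, r2$chi2)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("restricted BH-FDR matches the hand step-up and gates on raw p", {
  r <- fdr_bh_restricted(c(0.01, 0.02, 0.03, 0.8))
  expect_equal(r$q, c(0.04, 0.04, 0.04, 0.8))
  expect_equal(r$pass, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(fdr_bh_restricted(rep(1, 5))$pass))
  expect_equal(nrow(fdr_bh_restricted(numeric(0))), 0)
  set.seed(3)
  p <- runif(25)
  expect_equal(fdr_bh_restricted(p)$q, oracle_bh(p))
  # monotone: lowering q_max never adds discoveries
  pass_25 <- fdr_bh_restricted(p, q_max = 0.25)$pass
  pass_10 <- fdr_bh_restricted(p, q_max = 0.10)$pass
  expect_true(all(pass_25 | !pass_10))
  # the raw-p gate excludes cases BH alone would keep
  r2 <- fdr_bh_restricted(c(0.06, 0.06, 0.06, 0.06), q_max = 0.25)
  expect_false(any(r2$pass))
})

test_that("Spearman partial correlation reduces correctly and matches closed forms", {
  set.seed(4)
  x <- rnorm(50)
  y <- exp(x) # monotone transform
  expect_equal(spearman_partial(x, y)$rho, 1)
  z <- rnorm(50)
  expect_equal(spearman_partial(x, z)$rho,
               cor(x, z, method = "spearman"))
  # single covariate: closed-form partial correlation on Spearman r's
  n <- 12
  x <- rnorm(n); y <- rnorm(n); c1 <- rnorm(n)
  rxy <- cor(x, y, method = "spearman")
  rxz <- cor(x, c1, method = "spearman")
  ryz <- cor(y, c1, method = "spearman")
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(spearman_partial(x, y, cbind(c1))$rho, closed,
               tolerance = 1e-10)
  # two covariates: inverse-correlation-matrix identity
  c2 <- rnorm(n)
  P <- cor(apply(cbind(x, y, c1, c2), 2, rank))
  Pi <- solve(P)
  closed2 <- -Pi[1, 2] / sqrt(Pi[1, 1] * Pi[2, 2])
  expect_equal(spearman_partial(x, y, cbind(c1, c2))$rho, closed2,
               tolerance = 1e-10)
  expect_error(spearman_partial(rep(1, 20), rnorm(20)), "constant")
  expect_error(spearman_partial(rnorm(5), rnorm(5)), "at least 10")
})

test_that("Mauchly test and GG epsilon match car on the same model", {
  set.seed(5)
  n <- 30; k <- 4
  Y <- matrix(rnorm(n * k), n) %*% chol(0.4 + diag(0.6, k))
  colnames(Y) <- paste0("c", 1:k)
  ms <- mauchly_sphericity(Y, n_error = n - 1)
  mod <- lm(Y ~ 1)
  A <- car::Anova(mod, idata = data.frame(cond = factor(1:k)),
                  idesign = ~cond, type = 3)
  s <- summary(A, multivariate = FALSE)
  expect_equal(ms$W, unname(s$sphericity.tests["cond", "Test statistic"]),
               tolerance = 1e-8)
  expect_equal(ms$p, unname(s$sphericity.tests["cond", "p-value"]),
               tolerance = 2e-3)
  expect_equal(ms$gg_eps, unname(s$pval.adjustments["cond", "GG eps"]),
               tolerance = 1e-8)
  # compound symmetry -> epsilon near 1; bounds hold
  Ycs <- matrix(rnorm(200 * k), 200) %*% chol(matrix(0.5, k, k) + diag(0.5, k))
  eps <- mauchly_sphericity(Ycs)$gg_eps
  expect_gt(eps, 0.9)
  expect_lte(eps, 1)
  expect_gt(eps, 1 / (k - 1))
  expect_equal(mauchly_sphericity(Y[, 1:2])$gg_eps, 1)
})

test_that("rm_anova reports per-measure and omnibus effects with Bonferroni families", {
  f <- fake_stat_tbl(20, shift = c("NAcc-CEN" = 1.2), seed = 6)
  res <- rm_anova(f$tab, f$cov, family = "primary")
  expect_equal(res$family_size, 12)
  expect_equal(nrow(res$per_measure), 12)
  pm <- res$per_measure
  expect_true(all(pm$group_p_bonf >= pm$group_p - 1e-15))
  expect_true(all(pm$task_p_bonf <= 1) && all(pm$group_p_bonf <= 1))
  i <- pm$measure == "NAcc-CEN"
  expect_lt(pm$group_p_bonf[i], 0.05)
  expect_gt(min(pm$group_p[!i]), min(pm$group_p[i])) # effect is specific
  expect_true(all(pm$gg_eps > 0.2 & pm$gg_eps <= 1))
  # omnibus group test exists at n = 40 (12 DVs), task omnibus does not (60 DVs)
  expect_false(is.null(res$omnibus$group))
  expect_lt(res$omnibus$group$p, 0.05)
  expect_null(res$omnibus$task)
  # secondary family
  f2 <- fake_stat_tbl(15, measures = c("G_Eff", "G_Mod", "G_Res"), seed = 7)
  f2$tab$measure_class <- "secondary"
  res2 <- rm_anova(f2$tab, f2$cov, family = "secondary")
  expect_equal(res2$family_size, 3)
  expect_false(is.null(res2$omnibus$task)) # 15 contrast columns, n = 30
})

test_that("rm_anova excludes subjects with missing cells and reports them", {
  f <- fake_stat_tbl(12, seed = 8)
  f$tab$d_sd[f$tab$subject == "s003" & f$tab$condition == "C2"] <- NA
  res <- rm_anova(f$tab, f$cov, family = "primary")
  expect_equal(res$excluded_subjects, "s003")
  expect_equal(res$n_subjects, 23)
})

test_that("group-effect type-I error is near nominal under the null", {
  n_rep <- 200
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    f <- fake_stat_tbl(10, measures = "NAcc-CEN", seed = 1000 + r)
    f$tab$measure_class <- "primary"
    res <- rm_anova(f$tab, f$cov, family = "primary")
    if (res$per_measure$group_p[1] < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.11)
})

test_that("craving correlation grid has the right shape and restricted FDR", {
  f <- fake_stat_tbl(15, seed = 9)
  cc <- craving_correlations(f$tab, f$cov,
                             c("craving_prescan", "craving_duringscan"))
  expect_equal(nrow(cc), 144) # 12 measures x 6 conditions x 2 scores
  expect_true(all(abs(cc$rho) <= 1, na.rm = TRUE))
  expect_true(all(cc$pass == (cc$q <= 0.25 & cc$p < 0.05), na.rm = TRUE))
  # under the null the restricted-FDR discovery fraction stays small
  expect_lt(mean(cc$pass), 0.25)
})
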