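# Group-level inference: repeated-measures ANOVA (SPSS-style Type III,
# Greenhouse-Geisser adjustment, Bonferroni families of 12 primary / 3
# secondary measures), Mauchly's sphericity test, Spearman partial
# correlations with a restricted Benjamini-Hochberg FDR, and the
# summary-statistic demographic tests.

#' Welch's t statistic from group summaries
#'
#' Independent two-sample t with equal variances not assumed, computed
#' from means, SDs and group sizes, with the Welch-Satterthwaite degrees
#' of freedom.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 && sd2 <= 0) stop("at least one group must have sd > 0")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tt <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Pearson chi-square for a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param counts 2x2 matrix of non-negative counts with positive margins.
#' @return List with `chi2`, `df` and `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in counts")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - E)^2 / E)
  list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR with a raw-p restriction
#'
#' Step-up BH q-values over the whole family; a test passes only if its
#' q-value is at most `q_max` *and* its raw p-value is below `p_max`.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @param q_max FDR level (default 0.25).
#' @param p_max Raw-p gate (default 0.050).
#' @return Data frame with columns `p`, `q`, `pass`.
#' @export
fdr_bh_restricted <- function(pvals, q_max = 0.25, p_max = 0.050) {
  if (length(pvals) == 0)
    return(data.frame(p = numeric(0), q = numeric(0), pass = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, q = q, pass = !is.na(q) & q <= q_max & pvals < p_max)
}

#' Spearman partial correlation
#'
#' All variables are rank-transformed; the covariate ranks are removed
#' from `x` and `y` by least squares and the residuals are correlated.
#' With no covariates this reduces to the plain Spearman rho. The
#' p-value uses the t approximation with `n - 2 - q` degrees of freedom
#' (`q` = number of covariates).
#'
#' @param x,y Numeric vectors (n >= 10).
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @return List with `rho`, `p`, `n`, `df`.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & apply(is.finite(covariates), 1, all)
    covariates <- covariates[ok, , drop = FALSE]
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  rx <- rank(x); ry <- rank(y)
  q <- 0
  if (!is.null(covariates) && ncol(covariates) > 0) {
    rc <- apply(covariates, 2, rank)
    X <- cbind(1, rc)
    q <- ncol(covariates)
    rx <- stats::lm.fit(X, rx)$residuals
    ry <- stats::lm.fit(X, ry)$residuals
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - q
  tt <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df), n = n, df = df)
}

#' Mauchly's sphericity test and Greenhouse-Geisser epsilon
#'
#' Tests sphericity of the within-subject covariance over k >= 3
#' repeated levels on an orthonormal contrast basis, and returns the
#' Greenhouse-Geisser epsilon used to adjust the univariate F test.
#'
#' @param Y n x k matrix of repeated measures (one row per subject),
#'   or residuals thereof.
#' @param n_error Error degrees of freedom of the model the covariance
#'   comes from (default `nrow(Y) - 1`).
#' @return List with `W`, `chi2`, `df`, `p`, `gg_eps`.
#' @export
mauchly_sphericity <- function(Y, n_error = nrow(Y) - 1) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  if (k < 2) stop("need at least 2 repeated levels")
  if (k == 2) return(list(W = 1, chi2 = 0, df = 0, p = 1, gg_eps = 1))
  C <- contr_orthonormal(k)
  Sc <- t(C) %*% stats::cov(Y) %*% C
  kk <- k - 1
  ev <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  gg <- sum(ev)^2 / (kk * sum(ev^2))
  if (min(ev) <= 1e-12 * max(ev)) {
    warning("singular within-subject covariance; epsilon floored at 1/(k-1)")
    return(list(W = 0, chi2 = Inf, df = kk * (kk + 1) / 2 - 1, p = 0,
                gg_eps = 1 / kk))
  }
  W <- prod(ev) / (sum(ev) / kk)^kk
  d <- 1 - (2 * kk^2 + kk + 2) / (6 * kk * n_error)
  chi2 <- -n_error * d * log(W)
  df <- kk * (kk + 1) / 2 - 1
  list(W = W, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), gg_eps = gg)
}

contr_orthonormal <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Exact Wilks-lambda F test for a single-df coefficient row of a
# multivariate linear model.
wilks_row <- function(mod, row) {
  B <- stats::coef(mod)
  if (!is.matrix(B)) return(NULL) # univariate response: no Wilks test
  E <- crossprod(stats::residuals(mod))
  p <- ncol(B)
  df_e <- mod$df.residual
  if (df_e - p + 1 < 1) return(NULL) # not estimable at this n
  XtXinv <- solve(crossprod(stats::model.matrix(mod)))
  i <- match(row, rownames(B))
  if (is.na(i)) stop("no coefficient row '", row, "'")
  H <- tcrossprod(B[i, ]) / XtXinv[i, i]
  lambda <- det(E) / det(E + H)
  Fv <- (1 - lambda) / lambda * (df_e - p + 1) / p
  list(wilks = lambda, F = Fv, df1 = p, df2 = df_e - p + 1,
       p = stats::pf(Fv, p, df_e - p + 1, lower.tail = FALSE))
}

prep_covariates <- function(covariates) {
  stopifnot(all(c("subject", "group", "age", "mean_fd") %in%
                  names(covariates)))
  covariates$group <- factor(covariates$group)
  covariates$age_c <- covariates$age - mean(covariates$age)
  covariates$fd_c <- stats::ave(covariates$mean_fd,
                                covariates$group) # group means
  covariates$fd_c <- covariates$mean_fd - covariates$fd_c
  covariates
}

#' Repeated-measures ANOVA over task conditions with group and covariates
#'
#' For every measure in the chosen family, fits the SPSS-style
#' repeated-measures model: six within-subject task conditions, a
#' between-subject group factor, and age (grand-mean-centered) and mean
#' framewise displacement (mean-centered per group) as covariates
#' (Type III). Reports the Greenhouse-Geisser-adjusted univariate task
#' and interaction tests, Mauchly's test, the per-measure multivariate
#' (Wilks) task test, and the between-subject group test, with
#' Bonferroni correction over the family (12 primary connection
#' measures, 3 secondary topological measures). A multivariate omnibus
#' group test across the family's condition-mean profiles is computed
#' when the sample size permits.
#'
#' @param stat_tbl Long table from [stat_table()] (stacked over
#'   subjects): columns `subject`, `measure`, `measure_class`,
#'   `condition`, and the value column.
#' @param covariates Data frame with `subject`, `group`, `age`,
#'   `mean_fd`.
#' @param family `"primary"` or `"secondary"`.
#' @param value Value column to analyze (default `"d_sd"`).
#' @return List of class `rm_anova_result`: `per_measure` data frame,
#'   `omnibus` list, `family`, `family_size`, `n_subjects`,
#'   `excluded_subjects`.
#' @export
rm_anova <- function(stat_tbl, covariates, family = c("primary", "secondary"),
                     value = "d_sd") {
  family <- match.arg(family)
  measures <- if (family == "primary") connection_types() else
    c("G_Eff", "G_Mod", "G_Res")
  measures <- measures[measures %in% unique(stat_tbl$measure)]
  stat_tbl <- stat_tbl[stat_tbl$measure %in% measures, , drop = FALSE]
  if (nrow(stat_tbl) == 0) stop("no rows for family '", family, "'")
  covariates <- prep_covariates(covariates)
  conds <- names(condition_codes())
  m <- length(measures)

  # wide block per measure: subjects x 6 conditions
  wide_of <- function(meas) {
    d <- stat_tbl[stat_tbl$measure == meas, ]
    Y <- matrix(NA_real_, nrow(covariates), length(conds),
                dimnames = list(covariates$subject, conds))
    idx <- cbind(match(d$subject, covariates$subject),
                 match(d$condition, conds))
    Y[idx] <- d[[value]]
    Y
  }
  blocks <- lapply(measures, wide_of)
  names(blocks) <- measures
  complete <- Reduce(`&`, lapply(blocks, function(Y) apply(is.finite(Y), 1, all)))
  excluded <- covariates$subject[!complete]
  cv <- covariates[complete, , drop = FALSE]
  if (nrow(cv) < 8) stop("too few complete subjects (", nrow(cv), ")")
  idata <- data.frame(cond = factor(conds, levels = conds))

  rows <- vector("list", m)
  for (k in seq_len(m)) {
    Y <- blocks[[k]][complete, , drop = FALSE]
    mod <- stats::lm(Y ~ group + age_c + fd_c, data = cv)
    A <- car::Anova(mod, idata = idata, idesign = ~cond, type = 3)
    # (suppressed warning: unused Huynh-Feldt epsilon may exceed 1)
    s <- suppressWarnings(summary(A, multivariate = FALSE, univariate = TRUE))
    ut <- s$univariate.tests
    adj <- s$pval.adjustments
    sph <- s$sphericity.tests
    cell <- function(tab, i, j) {
      if (is.null(tab) || !i %in% rownames(tab)) NA_real_ else
        unname(tab[i, j])
    }
    gg <- cell(adj, "cond", "GG eps")
    # multivariate task test in the contrast space of this measure
    Cc <- contr_orthonormal(length(conds))
    modc <- stats::lm(Y %*% Cc ~ group + age_c + fd_c, data = cv)
    mv <- wilks_row(modc, "(Intercept)")
    gg_p <- cell(adj, "cond", "Pr(>F[GG])")
    rows[[k]] <- data.frame(
      measure = measures[k],
      mauchly_W = cell(sph, "cond", "Test statistic"),
      mauchly_p = cell(sph, "cond", "p-value"),
      gg_eps = gg,
      task_F = cell(ut, "cond", "F value"),
      task_df1 = cell(ut, "cond", "num Df") * gg,
      task_df2 = cell(ut, "cond", "den Df") * gg,
      task_p = if (is.na(gg_p)) cell(ut, "cond", "Pr(>F)") else gg_p,
      group_F = cell(ut, "group", "F value"),
      group_df1 = cell(ut, "group", "num Df"),
      group_df2 = cell(ut, "group", "den Df"),
      group_p = cell(ut, "group", "Pr(>F)"),
      interaction_F = cell(ut, "group:cond", "F value"),
      interaction_p = {
        ip <- cell(adj, "group:cond", "Pr(>F[GG])")
        if (is.na(ip)) cell(ut, "group:cond", "Pr(>F)") else ip
      },
      mv_task_F = if (is.null(mv)) NA_real_ else mv$F,
      mv_task_p = if (is.null(mv)) NA_real_ else mv$p,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  per$task_p_bonf <- pmin(1, m * per$task_p)
  per$group_p_bonf <- pmin(1, m * per$group_p)
  per$interaction_p_bonf <- pmin(1, m * per$interaction_p)

  # omnibus multivariate group test on condition-mean profiles
  M <- vapply(blocks, function(Y) rowMeans(Y[complete, , drop = FALSE]),
              numeric(nrow(cv)))
  modg <- stats::lm(M ~ group + age_c + fd_c, data = cv)
  lev <- levels(cv$group)
  om_group <- wilks_row(modg, paste0("group", lev[2]))
  # omnibus task/interaction over all measures' contrast columns
  Cc <- contr_orthonormal(length(conds))
  D <- do.call(cbind, lapply(blocks, function(Y)
    Y[complete, , drop = FALSE] %*% Cc))
  modd <- stats::lm(D ~ group + age_c + fd_c, data = cv)
  om_task <- wilks_row(modd, "(Intercept)")
  om_inter <- wilks_row(modd, paste0("group", lev[2]))

  structure(list(per_measure = per,
                 omnibus = list(group = om_group, task = om_task,
                                interaction = om_inter),
                 family = family, family_size = m,
                 n_subjects = nrow(cv), excluded_subjects = excluded),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("rm_anova (", x$family, " family, ", x$family_size, " measures, n = ",
      x$n_subjects, ")\n", sep = "")
  print(x$per_measure[, c("measure", "task_F", "task_p_bonf", "group_F",
                          "group_p", "group_p_bonf")], digits = 4)
  invisible(x)
}

#' Craving-connectivity correlation grid
#'
#' Spearman partial correlations (controlling age and mean framewise
#' displacement) between each measure x condition cell of the
#' task-weighted statistic and each craving score, within the user
#' group, with the restricted BH-FDR applied per family (measures x 6
#' conditions x craving scores: 144 primary cells, 36 secondary cells
#' for two craving scores).
#'
#' @param stat_tbl Long table from [stat_table()] stacked over subjects.
#' @param covariates Data frame with `subject`, `group`, `age`,
#'   `mean_fd`, plus one column per craving score (e.g.
#'   `craving_prescan`, `craving_duringscan`).
#' @param craving Names of the craving columns.
#' @param user_group Level of `group` defining the users.
#' @param family `"primary"` or `"secondary"`.
#' @param value Value column (default `"d_sd"`).
#' @param q_max,p_max Restricted-FDR parameters.
#' @return Data frame: `measure`, `condition`, `craving`, `rho`, `p`,
#'   `q`, `pass`.
#' @export
craving_correlations <- function(stat_tbl, covariates, craving,
                                 user_group = "CAN",
                                 family = c("primary", "secondary"),
                                 value = "d_sd", q_max = 0.25,
                                 p_max = 0.050) {
  family <- match.arg(family)
  measures <- if (family == "primary") connection_types() else
    c("G_Eff", "G_Mod", "G_Res")
  users <- covariates[covariates$group == user_group, , drop = FALSE]
  if (nrow(users) == 0) stop("no subjects in group '", user_group, "'")
  # craving scores are z-normalized within the user group (rank-invariant
  # for Spearman, applied for scale fidelity of reported values)
  for (cr in craving) {
    v <- users[[cr]]
    users[[cr]] <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  }
  conds <- names(condition_codes())
  grid <- expand.grid(measure = measures, condition = conds,
                      craving = craving, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    d <- stat_tbl[stat_tbl$measure == grid$measure[i] &
                    stat_tbl$condition == grid$condition[i], ]
    mi <- match(users$subject, d$subject)
    x <- d[[value]][mi]
    y <- users[[grid$craving[i]]]
    out <- tryCatch(
      spearman_partial(x, y, users[, c("age", "mean_fd")]),
      error = function(e) list(rho = NA_real_, p = NA_real_))
    c(rho = out$rho, p = out$p)
  })
  grid$rho <- vapply(res, `[[`, numeric(1), "rho")
  grid$p <- vapply(res, `[[`, numeric(1), "p")
  fdr <- fdr_bh_restricted(grid$p, q_max = q_max, p_max = p_max)
  grid$q <- fdr$q
  grid$pass <- fdr$pass
  grid
}
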