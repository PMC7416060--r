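# Two-stage quasi-maximum-likelihood dynamic conditional correlation:
# univariate GARCH(1,1) per region, then scalar DCC(1,1) with correlation
# targeting on the standardized residuals. No moving-average smoothing is
# applied at any point; the output has one correlation matrix per frame.

# Logistic map used by both stages: two unconstrained reals -> (a, b) with
# a, b >= 0 and a + b <= cap.
ab_from_theta <- function(theta, cap = 0.998) {
  e <- exp(theta - max(theta, 0))
  den <- exp(-max(theta, 0)) + sum(e)
  cap * e / den
}

theta_from_ab <- function(a, b, cap = 0.998) {
  pa <- a / cap
  pb <- b / cap
  p0 <- max(1 - pa - pb, 1e-8)
  log(c(max(pa, 1e-8), max(pb, 1e-8)) / p0)
}

#' Fit a univariate GARCH(1,1) model
#'
#' Gaussian quasi-maximum-likelihood estimation of
#' `h_t = omega + alpha x_{t-1}^2 + beta h_{t-1}` with `h_1` fixed at the
#' sample variance. The series is demeaned before fitting. Parameters are
#' optimized on a logistic transform enforcing `alpha, beta >= 0` and
#' `alpha + beta < 1`.
#'
#' @param x Numeric series (length >= 100, non-constant).
#' @param reltol Relative convergence tolerance for the optimizer.
#' @return List of class `garch_fit`: `omega`, `alpha`, `beta`,
#'   `log_likelihood` (the maximized Gaussian quasi-log-likelihood
#'   `sum(-0.5 (log h_t + x_t^2 / h_t))`), `h` (conditional variances),
#'   `converged`.
#' @export
fit_garch11 <- function(x, reltol = 1e-8) {
  x <- as.numeric(x)
  if (length(x) < 100) stop("series too short: need at least 100 frames")
  if (stats::var(x) <= 0 || !all(is.finite(x)))
    stop("zero-variance or non-finite series")
  x <- x - mean(x)
  scale_x <- stats::sd(x)
  x <- x / scale_x # unit variance: conditions the fit, exact scale equivariance
  h1 <- stats::var(x)
  starts <- list(c(0.05, 0.90), c(0.10, 0.60))
  best <- NULL
  for (s in starts) {
    p0 <- c(log(h1 * (1 - sum(s))), theta_from_ab(s[1], s[2]))
    opt <- garch11_fit_cpp(x, h1, p0, reltol, 2000L)
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0 && best$value < 1e9) break # fallback unneeded
  }
  ok <- best$convergence == 0 && best$value < 1e9
  if (!ok) {
    ll <- -garch11_negll_cpp(x, h1, 0, 0, h1) - length(x) * log(scale_x)
    return(structure(list(omega = h1 * scale_x^2, alpha = 0, beta = 0,
                          log_likelihood = ll,
                          h = rep(h1 * scale_x^2, length(x)),
                          converged = FALSE),
                     class = "garch_fit"))
  }
  ab <- ab_from_theta(best$theta[2:3])
  omega <- exp(best$theta[1])
  h <- as.numeric(garch11_filter_cpp(x, omega, ab[1], ab[2], h1))
  structure(list(omega = omega * scale_x^2, alpha = ab[1], beta = ab[2],
                 log_likelihood = -best$value - length(x) * log(scale_x),
                 h = h * scale_x^2, converged = TRUE),
            class = "garch_fit")
}

#' Evaluate the GARCH(1,1) quasi-log-likelihood at given parameters
#'
#' @param x Numeric series (demeaned internally).
#' @param omega,alpha,beta GARCH(1,1) parameters.
#' @return The Gaussian quasi-log-likelihood
#'   `sum(-0.5 (log h_t + x_t^2 / h_t))` with `h_1` at the sample
#'   variance.
#' @export
garch11_loglik <- function(x, omega, alpha, beta) {
  x <- as.numeric(x)
  x <- x - mean(x)
  -garch11_negll_cpp(x, omega, alpha, beta, stats::var(x))
}

#' Fit the scalar DCC(1,1) correlation model
#'
#' Second-stage quasi-maximum-likelihood with correlation targeting:
#' `Q_t = (1 - a - b) Qbar + a z_{t-1} z_{t-1}' + b Q_{t-1}`, `Q_1 = Qbar`
#' fixed at the sample correlation of the standardized residuals, and
#' `R_t = diag(Q_t)^{-1/2} Q_t diag(Q_t)^{-1/2}`. The two parameters are
#' optimized on a logistic transform from three standard starting points
#' ((0.02, 0.95), (0.05, 0.90), (0.10, 0.80)); ties are broken by
#' likelihood, then by the smaller `a`.
#'
#' @param Z Frames x regions matrix of standardized residuals.
#' @param reltol Optimizer relative tolerance.
#' @return List of class `dcc_fit`: `a`, `b`, `Qbar`, `log_likelihood`,
#'   `converged`.
#' @export
fit_dcc <- function(Z, reltol = 1e-7) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("Z contains non-finite values")
  if (nrow(Z) < ncol(Z) + 10)
    warning("ill-conditioned: fewer frames than regions + 10")
  Qbar <- stats::cor(Z)
  negll <- function(par) {
    ab <- ab_from_theta(par)
    dcc_negll_cpp(Z, Qbar, ab[1], ab[2])
  }
  starts <- list(c(0.02, 0.95), c(0.05, 0.90), c(0.10, 0.80))
  fits <- lapply(starts, function(s) {
    stats::optim(theta_from_ab(s[1], s[2]), negll, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = reltol))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  avals <- vapply(fits, function(f) ab_from_theta(f$par)[1], numeric(1))
  ord <- order(vals, avals)
  best <- fits[[ord[1]]]
  ok <- best$convergence == 0 && best$value < 1e9
  if (!ok) {
    return(structure(list(a = 0, b = 0, Qbar = Qbar,
                          log_likelihood = -dcc_negll_cpp(Z, Qbar, 0, 0),
                          converged = FALSE),
                     class = "dcc_fit"))
  }
  ab <- ab_from_theta(best$par)
  structure(list(a = ab[1], b = ab[2], Qbar = Qbar,
                 log_likelihood = -best$value, converged = TRUE),
            class = "dcc_fit")
}

#' Framewise correlation matrices implied by a DCC fit
#'
#' Runs the DCC recursion forward and returns the per-frame correlation
#' matrices.
#'
#' @param fit A `dcc_fit`.
#' @param Z The standardized-residual matrix the model was fit to.
#' @return `p x p x T` array of correlation matrices.
#' @export
dcc_correlations <- function(fit, Z) {
  stopifnot(inherits(fit, "dcc_fit"))
  dcc_filter_cpp(as.matrix(Z), fit$Qbar, fit$a, fit$b)
}

#' Framewise dynamic conditional correlations of a region time-series
#' matrix
#'
#' Composes the full two-stage estimator: per-region demeaning and
#' GARCH(1,1) fits, residual standardization, the scalar DCC(1,1) fit,
#' and the correlation recursion. No temporal smoothing is applied, so
#' the output has exactly one correlation matrix per input frame.
#'
#' With `factorization = "pairwise"` (the default) a bivariate DCC(1,1)
#' is fit independently for every unordered region pair, so each
#' connection carries its own innovation and persistence weights; this
#' is the appropriate choice for heterogeneous panels in which only some
#' connections fluctuate. `factorization = "joint"` fits one scalar
#' (a, b) over all regions via [fit_dcc()], which guarantees positive
#' semi-definite frames but shares a single dynamic across all pairs.
#'
#' @param X Frames x regions numeric matrix (column names are region
#'   ids); no missing values, at least 100 frames.
#' @param factorization `"pairwise"` (per-pair bivariate fits) or
#'   `"joint"` (one scalar fit over all regions).
#' @param reltol Optimizer tolerance passed to both stages.
#' @return Object of class `dcc_series`: list with `R` (p x p x T
#'   array), `regions`, `n_frames`, `n_regions`, `garch` (per-region
#'   parameter table), `dcc` (the `dcc_fit`, or the per-pair parameter
#'   matrices for the pairwise factorization) and `factorization`.
#' @export
dcc_series <- function(X, factorization = c("pairwise", "joint"),
                       reltol = 1e-7) {
  factorization <- match.arg(factorization)
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X))) stop("X contains missing values")
  if (nrow(X) < 100) stop("need at least 100 frames")
  regions <- colnames(X)
  if (is.null(regions)) regions <- paste0("r", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ", paste(regions[sds == 0], collapse = ", "))
  Xc <- sweep(X, 2, colMeans(X))
  gfits <- lapply(seq_len(ncol(Xc)), function(j)
    fit_garch11(Xc[, j], reltol = max(reltol, 1e-6)))
  Z <- vapply(seq_len(ncol(Xc)), function(j) Xc[, j] / sqrt(gfits[[j]]$h),
              numeric(nrow(Xc)))
  if (factorization == "joint") {
    dfit <- fit_dcc(Z, reltol = reltol)
    R <- dcc_filter_cpp(Z, dfit$Qbar, dfit$a, dfit$b)
  } else {
    starts <- rbind(c(0.02, 0.95), c(0.05, 0.90), c(0.10, 0.80))
    pw <- dcc_fit_pairwise_cpp(Z, starts, reltol = max(reltol, 1e-5),
                               maxit = 200)
    up <- upper.tri(pw$a)
    dfit <- structure(list(a = stats::median(pw$a[up]),
                           b = stats::median(pw$b[up]),
                           a_pairs = pw$a, b_pairs = pw$b,
                           log_likelihood = -sum(pw$negll[up]),
                           converged = TRUE),
                      class = "dcc_fit_pairwise")
    R <- pw$R
  }
  R <- array(R, dim = c(ncol(X), ncol(X), nrow(X)),
             dimnames = list(regions, regions, NULL))
  garch_tab <- data.frame(
    region = regions,
    omega = vapply(gfits, `[[`, numeric(1), "omega"),
    alpha = vapply(gfits, `[[`, numeric(1), "alpha"),
    beta = vapply(gfits, `[[`, numeric(1), "beta"),
    log_likelihood = vapply(gfits, `[[`, numeric(1), "log_likelihood"),
    converged = vapply(gfits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  structure(list(R = R, regions = regions, n_frames = nrow(X),
                 n_regions = ncol(X), garch = garch_tab, dcc = dfit,
                 factorization = factorization, Z = Z),
            class = "dcc_series")
}

#' @export
print.dcc_series <- function(x, ...) {
  cat("dcc_series (", x$factorization, "):", x$n_regions, "regions x",
      x$n_frames, "frames; a =", signif(x$dcc$a, 4), "b =",
      signif(x$dcc$b, 4),
      if (!x$dcc$converged) "(static fallback)", "\n")
  invisible(x)
}
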