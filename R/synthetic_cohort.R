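# Ground-truth generators. Two levels: (a) an exact forward simulator of
# the GARCH(1,1)/DCC(1,1) model for validating the estimator against its
# own data-generating process; (b) a latent-factor cohort generator in
# which the NAcc-CEN inter-factor correlation follows a stationary
# mean-reverting AR(1) whose fluctuation scale is elevated in the user
# group -- giving direct, interpretable control over the ground-truth
# connectivity variability -- plus craving scores coupled to it.

#' Simulate a GARCH(1,1)/DCC(1,1) process
#'
#' Exact forward simulation of the model the estimator assumes:
#' univariate GARCH(1,1) conditional variances and the scalar DCC
#' correlation recursion. Returns both the observations and the true
#' framewise correlation path.
#'
#' @param p Number of regions.
#' @param T Number of frames.
#' @param omega,alpha,beta GARCH(1,1) parameters (scalars, recycled).
#' @param a,b DCC parameters (`a + b < 1`).
#' @param Qbar Unconditional correlation matrix (default equicorrelation
#'   0.3).
#' @param seed RNG seed.
#' @return List with `X` (T x p observations), `R_true` (p x p x T),
#'   `h` (T x p conditional variances).
#' @export
simulate_garch_dcc <- function(p, T, omega = 0.1, alpha = 0.1, beta = 0.8,
                               a = 0.05, b = 0.90, Qbar = NULL,
                               seed = 1) {
  if (a < 0 || b < 0 || a + b >= 1) stop("need a, b >= 0 and a + b < 1")
  if (any(alpha + beta >= 1) || any(omega <= 0))
    stop("need omega > 0 and alpha + beta < 1")
  if (is.null(Qbar)) Qbar <- matrix(0.3, p, p) + diag(0.7, p)
  Qbar <- as.matrix(Qbar)
  if (nrow(Qbar) != p || max(abs(Qbar - t(Qbar))) > 1e-10 ||
      max(abs(diag(Qbar) - 1)) > 1e-10)
    stop("Qbar must be a p x p correlation matrix")
  ch <- tryCatch(chol(Qbar), error = function(e) NULL)
  if (is.null(ch)) stop("Qbar must be positive definite")
  omega <- rep(omega, length.out = p)
  alpha <- rep(alpha, length.out = p)
  beta <- rep(beta, length.out = p)
  set.seed(seed)
  X <- matrix(0, T, p)
  h <- matrix(0, T, p)
  R_true <- array(0, c(p, p, T))
  Q <- Qbar
  z_prev <- NULL
  h[1, ] <- omega / (1 - alpha - beta)
  for (t in seq_len(T)) {
    if (t > 1) {
      Q <- (1 - a - b) * Qbar + a * tcrossprod(z_prev) + b * Q
      h[t, ] <- omega + alpha * X[t - 1, ]^2 + beta * h[t - 1, ]
    }
    d <- 1 / sqrt(diag(Q))
    R <- Q * tcrossprod(d)
    R_true[, , t] <- R
    z <- drop(crossprod(chol(R), stats::rnorm(p)))
    X[t, ] <- sqrt(h[t, ]) * z
    z_prev <- z
  }
  list(X = X, R_true = R_true, h = h)
}

#' Cohort generator specification
#'
#' Collects the design and the data-generating parameters of the
#' synthetic two-group cohort. Defaults give a 21-region,
#' 810-frame/TR 2 s cue-exposure cohort of 20 controls and 20 users in
#' which the user group's NAcc-CEN latent-correlation innovation scale
#' is doubled and during-scan craving is coupled to the realized
#' variability.
#'
#' @param n_con,n_can Subjects per group (controls / users).
#' @param regions Named counts per network label.
#' @param design A [task_design] (default [canonical_cue_design()]).
#' @param base_cor Baseline correlation between network factors.
#' @param nacc_cen_mean Mean of the NAcc-CEN latent-correlation process
#'   (default 0: a weak, fluctuating subcortical-executive coupling
#'   whose variability, not its mean, differs between groups).
#' @param sigma_rho Stationary sd of the NAcc-CEN latent correlation
#'   (mean-reverting AR(1)) in the control group.
#' @param rho_ar AR(1) coefficient of the latent correlation (its
#'   fluctuation timescale is about `TR / (1 - rho_ar)` seconds).
#' @param multiplier Stationary-sd multiplier for the user group
#'   (>= 1).
#' @param subject_cv Coefficient of variation of the subject-level
#'   (trait) fluctuation scale: each subject's latent-correlation sd is
#'   the group value times a mean-preserving lognormal factor.
#' @param walk_bound Reflection bound guarding correlation validity.
#' @param noise_sd Region-level observation noise sd (factors have unit
#'   variance).
#' @param task_amplitude Amplitude of the stylized evoked response added
#'   along the cue-ON regressors.
#' @param coupling Coupling of during-scan craving to the subject's
#'   realized NAcc-CEN variability z-score.
#' @param craving_noise_sd Noise sd of the craving scores.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_con = 20, n_can = 20,
                        regions = c(DMN = 6, CEN = 5, SN = 6, Amyg = 2,
                                    NAcc = 2),
                        design = NULL, base_cor = 0.3, nacc_cen_mean = 0,
                        sigma_rho = 0.15, rho_ar = 0.95, multiplier = 2,
                        subject_cv = 0.2, walk_bound = 0.85, noise_sd = 0.8,
                        task_amplitude = 0.3, coupling = 1,
                        craving_noise_sd = 0.75) {
  if (multiplier < 1) stop("multiplier must be >= 1")
  if (n_con < 2 || n_can < 2) stop("need at least 2 subjects per group")
  needed <- c("DMN", "CEN", "SN", "Amyg", "NAcc")
  if (!all(needed %in% names(regions)) || any(regions[needed] < 2))
    stop("regions must name DMN, CEN, SN, Amyg, NAcc with counts >= 2")
  if (walk_bound <= 0 || walk_bound >= 1) stop("walk_bound must be in (0,1)")
  if (rho_ar < 0 || rho_ar >= 1) stop("rho_ar must be in [0, 1)")
  if (is.null(design)) design <- canonical_cue_design()
  structure(list(n_con = n_con, n_can = n_can, regions = regions,
                 design = design, base_cor = base_cor,
                 nacc_cen_mean = nacc_cen_mean,
                 sigma_rho = sigma_rho, rho_ar = rho_ar,
                 multiplier = multiplier, subject_cv = subject_cv,
                 walk_bound = walk_bound,
                 noise_sd = noise_sd, task_amplitude = task_amplitude,
                 coupling = coupling, craving_noise_sd = craving_noise_sd),
            class = "cohort_spec")
}

# Reflect a value into [-b, b].
reflect <- function(x, b) {
  while (abs(x) > b) x <- sign(x) * (2 * b) - x
  x
}

#' Simulated motion, physiological and framewise-displacement confounds
#'
#' Six motion parameters as smooth random walks, three physiological
#' signals as AR(1) processes, and a non-negative framewise-displacement
#' series with occasional spikes above 0.5 mm.
#'
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return Data frame with columns `motion1`..`motion6`,
#'   `physio1`..`physio3`, `fd`.
#' @export
simulate_confounds <- function(n_frames, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(seed)
  motion <- vapply(1:6, function(j) cumsum(stats::rnorm(n_frames, 0, 0.02)),
                   numeric(n_frames))
  physio <- vapply(1:3, function(j) {
    x <- numeric(n_frames)
    for (t in 2:max(2, n_frames))
      x[t] <- 0.95 * x[t - 1] + stats::rnorm(1, 0, 0.1)
    x
  }, numeric(n_frames))
  fd <- abs(stats::rnorm(n_frames, 0.1, 0.06))
  spikes <- stats::runif(n_frames) < 0.02
  fd[spikes] <- fd[spikes] + stats::runif(sum(spikes), 0.45, 1)
  out <- data.frame(motion, physio, fd)
  names(out) <- c(paste0("motion", 1:6), paste0("physio", 1:3), "fd")
  out
}

#' Simulate a two-group cue-exposure cohort with known ground truth
#'
#' Each subject's region series arise from five network factors (DMN,
#' CEN, SN, Amyg, NAcc) with baseline inter-factor correlation
#' `base_cor`; the NAcc-CEN factor correlation follows a stationary
#' mean-reverting AR(1) process around `nacc_cen_mean` whose stationary
#' sd is `sigma_rho` (times the subject's trait factor) for controls
#' and `multiplier` times that for users, reflected at `walk_bound` to
#' stay a valid correlation. Regions add white observation
#' noise and a stylized evoked response along the cue-ON regressors.
#' During-scan craving is `coupling` times the subject's realized
#' NAcc-CEN variability z-score plus noise; prescan craving is
#' uncoupled noise. Age and mean framewise displacement are drawn from
#' fixed normals; per-subject confound tables are generated with
#' [simulate_confounds()].
#'
#' @param spec A [cohort_spec].
#' @param seed Master seed; per-subject child seeds are spawned from it
#'   deterministically.
#' @return List of class `synthetic_cohort`: `subjects` (list with `id`,
#'   `group`, `X`, `confounds`, `seed`), `membership`, `design`,
#'   `covariates`, `ground_truth` (per-subject per-condition true
#'   variability of the latent NAcc-CEN correlation), `rho_paths`
#'   (frames x subjects), `spec`, `seed`.
#' @export
simulate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  design <- spec$design
  n_frames <- design$n_frames
  nets <- c("DMN", "CEN", "SN", "Amyg", "NAcc")
  counts <- spec$regions[nets]
  region_id <- unlist(lapply(nets, function(k)
    paste0(k, "_", seq_len(counts[[k]]))))
  membership <- roi_membership(region_id,
                               rep(nets, times = counts))
  n <- spec$n_con + spec$n_can
  groups <- rep(c("CON", "CAN"), c(spec$n_con, spec$n_can))
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1, n)
  ids <- sprintf("sub%03d", seq_len(n))

  # evoked response: cue-ON regressors with network-specific gains
  weights <- condition_weights(design)
  H_on <- Reduce(`+`, lapply(c("C1", "C2", "C3"), function(cc)
    weights[[cc]]$H$values))
  gains <- c(DMN = -0.5, CEN = 0.5, SN = 1, Amyg = 1, NAcc = 1)
  evoked <- spec$task_amplitude * outer(H_on, gains[membership$network])

  iN <- match(c("DMN", "CEN", "SN", "Amyg", "NAcc"), nets)
  i_cen <- which(nets == "CEN")
  i_nacc <- which(nets == "NAcc")
  base_C <- matrix(spec$base_cor, 5, 5)
  diag(base_C) <- 1

  t_frame <- (seq_len(n_frames) - 0.5) * design$TR
  subjects <- vector("list", n)
  rho_paths <- matrix(0, n_frames, n)
  for (s in seq_len(n)) {
    set.seed(subject_seeds[s])
    trait <- exp(stats::rnorm(1, -spec$subject_cv^2 / 2, spec$subject_cv))
    sd_s <- spec$sigma_rho * trait *
      if (groups[s] == "CAN") spec$multiplier else 1
    phi <- spec$rho_ar
    mu <- spec$nacc_cen_mean
    sd_inn <- sd_s * sqrt(1 - phi^2)
    rho <- numeric(n_frames)
    rho[1] <- reflect(mu + stats::rnorm(1, 0, sd_s), spec$walk_bound)
    steps <- stats::rnorm(n_frames - 1, 0, sd_inn)
    for (t in 2:n_frames)
      rho[t] <- reflect(mu + phi * (rho[t - 1] - mu) + steps[t - 1],
                        spec$walk_bound)
    rho_paths[, s] <- rho
    f <- matrix(0, n_frames, 5)
    for (t in seq_len(n_frames)) {
      C <- base_C
      C[i_cen, i_nacc] <- C[i_nacc, i_cen] <- rho[t]
      ch <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(ch)) { # eigenvalue floor, then renormalize to unit diag
        e <- eigen(C, symmetric = TRUE)
        C <- e$vectors %*% diag(pmax(e$values, 1e-6)) %*% t(e$vectors)
        C <- stats::cov2cor(C)
        ch <- chol(C)
      }
      f[t, ] <- crossprod(ch, stats::rnorm(5))
    }
    X <- f[, match(membership$network, nets)] +
      matrix(stats::rnorm(n_frames * nrow(membership), 0, spec$noise_sd),
             n_frames) + evoked
    colnames(X) <- membership$region_id
    confounds <- simulate_confounds(n_frames, seed = subject_seeds[s] %% 1e6)
    subjects[[s]] <- list(id = ids[s], group = groups[s], X = X,
                          confounds = confounds, seed = subject_seeds[s])
  }

  # ground truth: per-condition SD of the latent correlation path
  codes <- names(condition_codes())
  gt <- do.call(rbind, lapply(codes, function(cc) {
    frames <- unlist(lapply(weights[[cc]]$windows, `[[`, "frames"))
    data.frame(subject = ids, condition = cc,
               true_sd = apply(rho_paths[frames, , drop = FALSE], 2, stats::sd),
               stringsAsFactors = FALSE)
  }))
  overall_sd <- apply(rho_paths, 2, stats::sd)
  zvar <- (overall_sd - mean(overall_sd)) / stats::sd(overall_sd)

  set.seed(seed + 1L)
  covariates <- data.frame(
    subject = ids, group = groups,
    age = pmax(18, stats::rnorm(n, 29.4, 9.2)),
    mean_fd = vapply(subjects, function(su) mean(su$confounds$fd),
                     numeric(1)),
    craving_prescan = stats::rnorm(n, 0, 1),
    craving_duringscan = spec$coupling * zvar +
      stats::rnorm(n, 0, spec$craving_noise_sd),
    true_sd_overall = overall_sd,
    stringsAsFactors = FALSE)

  structure(list(subjects = subjects, membership = membership,
                 design = design, covariates = covariates,
                 ground_truth = gt, rho_paths = rho_paths, spec = spec,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$subjects), "subjects (",
      x$spec$n_con, "CON /", x$spec$n_can, "CAN ),",
      nrow(x$membership), "regions,", x$design$n_frames, "frames\n")
  invisible(x)
}

#' One end-to-end recovery replicate
#'
#' Simulates a cohort, runs the estimator, summary and task-statistic
#' stages, and returns the group-inference quantities for one connection
#' measure: the Bonferroni-corrected (family of 12) and uncorrected
#' between-group p-values from the repeated-measures model, and the
#' Spearman partial correlation (age and mean FD controlled) between
#' during-scan craving and the measure's condition-mean d_SD within the
#' user group.
#'
#' @param spec A [cohort_spec].
#' @param seed Replicate seed.
#' @param measure Connection measure to report (default `"NAcc-CEN"`).
#' @param weights Optional precomputed [condition_weights()] for the
#'   spec's design.
#' @return List with `p_group_bonf`, `p_group`, `craving_rho`,
#'   `mean_dsd_con`, `mean_dsd_can`.
#' @export
cohort_recovery <- function(spec, seed, measure = "NAcc-CEN",
                            weights = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(weights)) weights <- condition_weights(spec$design)
  co <- simulate_cohort(spec, seed = seed)
  tabs <- lapply(co$subjects, function(su) {
    fit <- dcc_series(su$X)
    summ <- summarize_series(fit, co$membership)
    stat_table(summ, co$design, subject = su$id, weights = weights)
  })
  tab <- do.call(rbind, tabs)
  an <- rm_anova(tab, co$covariates, family = "primary")
  pm <- an$per_measure
  i <- match(measure, pm$measure)
  d <- tab[tab$measure == measure, ]
  dsd <- tapply(d$d_sd, d$subject, mean)[co$covariates$subject]
  can <- co$covariates$group == "CAN"
  sp <- tryCatch(
    spearman_partial(dsd[can], co$covariates$craving_duringscan[can],
                     co$covariates[can, c("age", "mean_fd")]),
    error = function(e) list(rho = NA_real_))
  list(p_group_bonf = pm$group_p_bonf[i], p_group = pm$group_p[i],
       craving_rho = sp$rho,
       mean_dsd_con = mean(dsd[!can]), mean_dsd_can = mean(dsd[can]))
}
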