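test_that("canonical HRF has the expected shape and analytic derivative", {
  k <- canonical_hrf(0.01, span = 32)
  expect_identical(k$hrf[1], 0)
  expect_lt(abs(k$time[which.max(k$hrf)] - 5), 0.1)
  # analytic derivative vs central finite differences
  k2 <- canonical_hrf(0.1)
  fd <- (k2$hrf[-(1:2)] - k2$hrf[seq_len(length(k2$hrf) - 2)]) / 0.2
  expect_lt(max(abs(k2$deriv[-c(1, length(k2$deriv))] - fd)), 1e-3)
  expect_error(canonical_hrf(0), "positive")
})

test_that("canonical cue design reproduces the two-session trial structure", {
  d <- canonical_cue_design()
  expect_equal(d$n_frames, 810)
  expect_equal(d$TR, 2)
  ev <- d$events
  for (ct in c("neutral", "natural_reward", "cannabis")) {
    expect_equal(sum(ev$trial_type == paste0(ct, "_on")), 12)
    expect_equal(sum(ev$trial_type == paste0(ct, "_rate")), 12)
    expect_equal(sum(ev$trial_type == paste0(ct, "_off")), 12)
  }
  expect_true(all(ev$duration[grepl("_rate$", ev$trial_type)] == 5))
  expect_true(all(ev$duration[!grepl("_rate$", ev$trial_type)] == 20))
  # sessions are balanced: 6 trials per cue type in each 13.5-min half
  on1 <- ev[grepl("_on$", ev$trial_type) & ev$onset < 810, ]
  expect_equal(as.vector(table(on1$trial_type)), rep(6L, 3))
})

test_that("condition regressor matches a direct discrete convolution", {
  ev <- data.frame(onset = 0, duration = 20, trial_type = "cannabis_on")
  d <- task_design(ev, TR = 2, n_frames = 30)
  reg <- build_condition_regressor(d, "cannabis_on", oversample = 1,
                                   t_ref = 0)
  k <- canonical_hrf(2)
  box <- rep(c(1, 0), c(10, 20))
  direct <- sapply(seq_len(30), function(n) {
    idx <- seq_len(min(n, length(k$hrf)))
    sum(k$hrf[idx] * box[n - idx + 1]) * 2
  })
  expect_lt(max(abs(reg$values - direct)), 1e-12)
  expect_false(reg$is_mean_centered)
})

test_that("regressor of the canonical design has full length and zero-event conditions give zeros", {
  d <- canonical_cue_design()
  reg <- build_condition_regressor(d, "C3")
  expect_length(reg$values, 810)
  ev <- data.frame(onset = 10, duration = 20, trial_type = "neutral_on")
  d2 <- task_design(ev, TR = 2, n_frames = 50)
  z <- build_condition_regressor(d2, "cannabis_on")
  expect_identical(z$values, numeric(50))
  expect_error(build_condition_regressor(d2, "not_a_condition"),
               "missing condition")
})

test_that("regressors are linear in the event set", {
  e1 <- data.frame(onset = 10, duration = 20, trial_type = "cannabis_on")
  e2 <- data.frame(onset = 120, duration = 20, trial_type = "cannabis_on")
  d12 <- task_design(rbind(e1, e2), TR = 2, n_frames = 120)
  d1 <- task_design(e1, TR = 2, n_frames = 120)
  d2 <- task_design(e2, TR = 2, n_frames = 120)
  v12 <- build_condition_regressor(d12, "C3")$values
  v1 <- build_condition_regressor(d1, "C3")$values
  v2 <- build_condition_regressor(d2, "C3")$values
  expect_lt(max(abs(v12 - (v1 + v2))), 1e-10)
})

test_that("trial windows: counts, positivity, disjointness and tail length", {
  d <- canonical_cue_design()
  for (cc in names(condition_codes())) {
    w <- extract_trial_windows(d, cc)
    expect_length(w, 12)
    H <- build_condition_regressor(d, cc)$values
    frames <- unlist(lapply(w, `[[`, "frames"))
    expect_false(anyDuplicated(frames) > 0)
    expect_true(all(H[frames] > 1e-6))
    expect_true(all(vapply(w, `[[`, integer(1), "T1") >= 2))
  }
  # a single 20 s trial's window runs past the 10-frame block (HRF tail)
  ev <- data.frame(onset = 0, duration = 20, trial_type = "cannabis_on")
  d1 <- task_design(ev, TR = 2, n_frames = 40)
  w1 <- extract_trial_windows(d1, "C3")
  expect_gt(w1[[1]]$T1, 10)
  # no events -> degenerate-window error
  expect_error(extract_trial_windows(d1, "C1"), "degenerate window")
})

test_that("task nuisance design has 18 mean-centered columns (12 without rating events)", {
  d <- canonical_cue_design()
  X <- build_task_nuisance_design(d)
  expect_equal(ncol(X), 18)
  expect_lt(max(abs(colMeans(X))), 1e-12)
  expect_false(attr(X, "rate_fallback"))
  d_norate <- task_design(d$events[!grepl("_rate$", d$events$trial_type), ],
                          TR = 2, n_frames = 810)
  expect_warning(X12 <- build_task_nuisance_design(d_norate), "rating")
  expect_equal(ncol(X12), 12)
  expect_true(attr(X12, "rate_fallback"))
  d_empty <- task_design(d$events[0, ], TR = 2, n_frames = 10)
  expect_warning(X0 <- build_task_nuisance_design(d_empty), "no task events")
  expect_equal(ncol(X0), 0)
})

test_that("confound expansion follows the 36-regressor scheme with FD spikes", {
  set.seed(1)
  n <- 60
  motion <- matrix(rnorm(6 * n), n)
  physio <- matrix(rnorm(3 * n), n)
  X <- expand_confounds(motion, physio)
  expect_equal(ncol(X), 36)
  expect_lt(max(abs(colMeans(X))), 1e-12)
  # constant input column -> zero derivative column
  motion2 <- motion
  motion2[, 3] <- 1
  X2 <- expand_confounds(motion2, physio)
  expect_identical(unname(X2[, "motion3.d"]), rep(0, n))
  # squared column equals recentered square of the centered input
  sq <- scale(scale(motion[, 2], scale = FALSE)^2, scale = FALSE)
  expect_lt(max(abs(X[, "motion2.sq"] - sq)), 1e-12)
  # FD spikes
  fd <- rep(0.1, n)
  fd[c(5, 20)] <- 0.9
  X3 <- expand_confounds(motion, physio, fd = fd)
  expect_equal(attr(X3, "spike_frames"), c(5, 20))
  expect_equal(colSums(attr(X3, "spikes")), c(spike5 = 1, spike20 = 1))
  expect_error(expand_confounds(motion[, 1:5], physio), "6 columns")
  expect_error(expand_confounds(motion, physio[, 1:2]), "3 columns")
})
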