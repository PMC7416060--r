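#' @useDynLib dynconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var sd cor lm lm.fit pchisq pf pt rnorm runif
#' @importFrom utils read.delim write.table
NULL

CUE_TYPES <- c("neutral", "natural_reward", "cannabis")
PHASES <- c("on", "off", "rate")

#' Condition code table for the cue-exposure design
#'
#' Maps the six analysis condition codes (C1, W1, C2, W2, C3, W3) to
#' event labels: C = cue ON, W = cue OFF (washout), for neutral,
#' natural-reward and cannabis cues respectively. Rating periods are
#' nuisance-only and carry no code.
#'
#' @return Named character vector; names are codes, values are
#'   `trial_type` labels such as `"cannabis_on"`.
#' @export
condition_codes <- function() {
  c(C1 = "neutral_on", W1 = "neutral_off",
    C2 = "natural_reward_on", W2 = "natural_reward_off",
    C3 = "cannabis_on", W3 = "cannabis_off")
}

# Resolve a user-supplied condition (code or label) to a trial_type label.
resolve_condition <- function(condition) {
  codes <- condition_codes()
  if (condition %in% names(codes)) return(unname(codes[condition]))
  condition
}

all_stream_labels <- function() {
  as.vector(t(outer(CUE_TYPES, PHASES, paste, sep = "_")))
}

#' Construct a task design
#'
#' Bundles an events table with the acquisition grid (repetition time and
#' frame count). Events are sorted by onset and validated against the scan
#' duration.
#'
#' @param events Data frame with columns `onset` (s, >= 0), `duration`
#'   (s, > 0) and `trial_type` (character label).
#' @param TR Repetition time in seconds.
#' @param n_frames Number of acquired frames.
#' @return An object of class `task_design`.
#' @export
task_design <- function(events, TR, n_frames) {
  stopifnot(is.data.frame(events),
            all(c("onset", "duration", "trial_type") %in% names(events)))
  if (TR <= 0) stop("TR must be positive")
  if (n_frames < 1) stop("n_frames must be at least 1")
  if (any(!is.finite(events$onset)) || any(events$onset < 0))
    stop("event onsets must be finite and non-negative")
  if (any(!is.finite(events$duration)) || any(events$duration <= 0))
    stop("event durations must be positive")
  total <- n_frames * TR
  if (any(events$onset + events$duration > total + 1e-9))
    stop("events extend past the end of the scan (", total, " s)")
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, TR = TR, n_frames = n_frames),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("task_design:", x$n_frames, "frames, TR", x$TR, "s,",
      nrow(x$events), "events over", length(unique(x$events$trial_type)),
      "conditions\n")
  invisible(x)
}

# Frozen pseudorandom cue order for the canonical two-session program:
# each row is one 18-trial session, balanced 6 trials per cue type.
CANONICAL_ORDER <- rbind(
  c(2, 3, 1, 1, 3, 2, 3, 1, 2, 2, 1, 3, 1, 2, 3, 3, 2, 1),
  c(3, 1, 2, 2, 3, 1, 1, 2, 3, 3, 1, 2, 2, 3, 1, 1, 3, 2))

#' Canonical cue-exposure design
#'
#' Two back-to-back 13.5-min sessions; each cue type (neutral, natural
#' reward, cannabis) is shown for 12 trials of 20 s, each trial followed
#' by a 5 s rating period and a 20 s washout, so 36 trials of 45 s fill
#' 27 min = 810 frames at TR 2 s. The trial order is a fixed balanced
#' pseudorandom interleaving, identical for every subject.
#'
#' @param TR Repetition time in seconds (default 2).
#' @param n_trials Trials per cue type (default 12; must be a multiple of
#'   the number of cue types' session balance, i.e. even).
#' @return A [task_design].
#' @export
canonical_cue_design <- function(TR = 2, n_trials = 12) {
  if (n_trials == 12) {
    order <- as.vector(t(CANONICAL_ORDER))
  } else {
    # generic balanced interleaving for non-canonical trial counts
    order <- rep(seq_along(CUE_TYPES), n_trials)
  }
  trial_len <- 45 # 20 s cue + 5 s rate + 20 s washout
  ev <- do.call(rbind, lapply(seq_along(order), function(i) {
    on0 <- (i - 1) * trial_len
    cue <- CUE_TYPES[order[i]]
    data.frame(onset = c(on0, on0 + 20, on0 + 25),
               duration = c(20, 5, 20),
               trial_type = paste(cue, c("on", "rate", "off"), sep = "_"),
               stringsAsFactors = FALSE)
  }))
  n_frames <- length(order) * trial_len / TR
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop("TR does not divide the trial length evenly")
  task_design(ev, TR = TR, n_frames = round(n_frames))
}

#' Canonical double-gamma HRF kernel
#'
#' Samples the canonical haemodynamic response (difference of two gamma
#' densities: response peak 6 s, undershoot peak 16 s, unit dispersions,
#' undershoot ratio 1/6) and its analytic temporal derivative on the grid
#' `{0, dt, 2 dt, ...}` up to `span` seconds.
#'
#' @param dt Sampling step in seconds (> 0).
#' @param span Kernel support in seconds (>= 32 recommended).
#' @return List of class `hrf_kernel` with elements `time`, `hrf`,
#'   `deriv` and `dt`.
#' @export
canonical_hrf <- function(dt, span = 32) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a positive scalar")
  tt <- seq(0, span, by = dt)
  g <- function(t, a) stats::dgamma(t, shape = a, rate = 1)
  h <- g(tt, 6) - g(tt, 16) / 6
  # d/dt dgamma(t, a, 1) = dgamma(t, a, 1) * ((a - 1)/t - 1); 0 at t = 0
  dg <- function(t, a) ifelse(t > 0, g(t, a) * ((a - 1) / t - 1), 0)
  dh <- dg(tt, 6) - dg(tt, 16) / 6
  structure(list(time = tt, hrf = h, deriv = dh, dt = dt),
            class = "hrf_kernel")
}

# Oversampled boxcar of a set of events, convolved with a kernel vector and
# sampled back onto the frame grid. `t_ref` is the within-frame reference
# point as a fraction of TR (0 = frame onset, 0.5 = frame midpoint).
convolve_events <- function(events, TR, n_frames, kernel_values, dt,
                            t_ref = 0.5) {
  n_fine <- ceiling(n_frames * TR / dt)
  box <- numeric(n_fine)
  t_fine <- (seq_len(n_fine) - 1) * dt
  for (k in seq_len(nrow(events))) {
    on <- events$onset[k]
    box[t_fine >= on - 1e-12 & t_fine < on + events$duration[k] - 1e-12] <- 1
  }
  nk <- length(kernel_values)
  conv <- stats::filter(c(numeric(nk - 1), box), kernel_values,
                        method = "convolution", sides = 1)
  conv <- as.numeric(conv)[nk:(nk - 1 + n_fine)] * dt
  t_frame <- (seq_len(n_frames) - 1 + t_ref) * TR
  idx <- pmin(n_fine, floor(t_frame / dt + 1e-9) + 1)
  conv[idx]
}

#' HRF-convolved condition regressor
#'
#' Builds the boxcar of all events of one condition at an oversampled
#' resolution, convolves it with the canonical HRF and samples the result
#' at the frame reference times. The regressor is *not* mean-centered:
#' it is the weighting series H_task used by the task-modulated
#' statistics.
#'
#' @param design A [task_design].
#' @param condition Condition code (`"C3"`) or event label
#'   (`"cannabis_on"`).
#' @param oversample Oversampling factor; the fine grid step is
#'   `TR / oversample` (default 16).
#' @param t_ref Within-frame sampling reference as a fraction of TR
#'   (default 0.5, the frame midpoint).
#' @param derivative If `TRUE`, convolve with the HRF temporal derivative
#'   instead.
#' @return Object of class `condition_regressor`: list with `condition`,
#'   `values` (length `n_frames`) and `is_mean_centered = FALSE`.
#' @export
build_condition_regressor <- function(design, condition, oversample = 16,
                                      t_ref = 0.5, derivative = FALSE) {
  stopifnot(inherits(design, "task_design"))
  label <- resolve_condition(condition)
  known <- union(all_stream_labels(), unique(design$events$trial_type))
  if (!label %in% known)
    stop("missing condition: '", condition, "' is not a known condition")
  ev <- design$events[design$events$trial_type == label, , drop = FALSE]
  dt <- design$TR / oversample
  kern <- canonical_hrf(dt)
  kv <- if (derivative) kern$deriv else kern$hrf
  values <- if (nrow(ev) == 0) numeric(design$n_frames) else
    convolve_events(ev, design$TR, design$n_frames, kv, dt, t_ref)
  structure(list(condition = label, values = values,
                 is_mean_centered = FALSE),
            class = "condition_regressor")
}

regressor_values <- function(H) {
  if (inherits(H, "condition_regressor")) H$values else as.numeric(H)
}

#' Trial windows of a condition
#'
#' Each trial's boxcar is convolved with the HRF separately; the trial
#' window is the set of frames where that trial's response exceeds
#' `epsilon`, clipped at the onset of the next trial of the same condition
#' and at the end of the scan. One window per trial is returned.
#'
#' @inheritParams build_condition_regressor
#' @param epsilon Positivity tolerance for "nonzero positive" response
#'   (default 1e-6).
#' @return List of class `trial_window` elements: `condition`,
#'   `trial_index`, `frames` (1-based, strictly increasing) and `T1`.
#' @export
extract_trial_windows <- function(design, condition, epsilon = 1e-6,
                                  oversample = 16, t_ref = 0.5) {
  stopifnot(inherits(design, "task_design"))
  if (epsilon <= 0) stop("epsilon must be positive")
  label <- resolve_condition(condition)
  ev <- design$events[design$events$trial_type == label, , drop = FALSE]
  if (nrow(ev) == 0)
    stop("degenerate window: condition '", condition, "' has no events")
  dt <- design$TR / oversample
  kern <- canonical_hrf(dt)
  span <- max(kern$time)
  t_frame <- (seq_len(design$n_frames) - 1 + t_ref) * design$TR
  # the condition's full regressor: a neighbouring trial's undershoot can
  # pull H_task below epsilon inside a trial's own response support, and
  # such frames carry no positive weight
  H_full <- convolve_events(ev, design$TR, design$n_frames, kern$hrf, dt,
                            t_ref)
  windows <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    # convolve only the local stretch the trial's response can reach
    f0 <- max(0, floor(ev$onset[k] / design$TR) - 1)
    f1 <- min(design$n_frames,
              ceiling((ev$onset[k] + ev$duration[k] + span) / design$TR) + 1)
    sub <- data.frame(onset = ev$onset[k] - f0 * design$TR,
                      duration = ev$duration[k],
                      trial_type = ev$trial_type[k])
    v <- convolve_events(sub, design$TR, f1 - f0, kern$hrf, dt, t_ref)
    frames <- which(v > epsilon) + f0
    frames <- frames[H_full[frames] > epsilon]
    if (k < nrow(ev)) frames <- frames[t_frame[frames] < ev$onset[k + 1]]
    if (length(frames) < 2)
      stop("degenerate window: trial ", k, " of '", label,
           "' has fewer than 2 frames above epsilon")
    windows[[k]] <- structure(
      list(condition = label, trial_index = k, frames = frames,
           T1 = length(frames)),
      class = "trial_window")
  }
  windows
}

#' Task nuisance design matrix
#'
#' Mean-centered HRF-convolved regressors and their derivative-convolved
#' counterparts for every condition stream present in the design (three
#' cue types x ON/OFF/RATE x {HRF, derivative} = 18 columns for the
#' canonical design). If no rating events are present a 12-column
#' fallback is returned with a warning and attribute
#' `rate_fallback = TRUE`.
#'
#' @inheritParams build_condition_regressor
#' @return Numeric matrix with `n_frames` rows and named columns.
#' @export
build_task_nuisance_design <- function(design, oversample = 16, t_ref = 0.5) {
  stopifnot(inherits(design, "task_design"))
  streams <- all_stream_labels()
  present <- streams[streams %in% design$events$trial_type]
  if (length(present) == 0) {
    warning("design contains no task events; returning 0-column matrix")
    return(matrix(numeric(0), nrow = design$n_frames, ncol = 0))
  }
  rate_fallback <- !any(grepl("_rate$", present))
  if (rate_fallback) {
    warning("no rating events found; returning ON/OFF-only nuisance design")
  }
  cols <- lapply(present, function(s) {
    h <- build_condition_regressor(design, s, oversample, t_ref)$values
    d <- build_condition_regressor(design, s, oversample, t_ref,
                                   derivative = TRUE)$values
    cbind(h - mean(h), d - mean(d))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- as.vector(t(outer(present, c("hrf", "deriv"), paste,
                                   sep = ".")))
  attr(X, "rate_fallback") <- rate_fallback
  X
}

center <- function(x) x - mean(x)

#' Expanded confound regressors
#'
#' Applies the standard 4-term expansion to six motion parameters and
#' three physiological signals: mean-centered value, mean-centered
#' derivative, mean-centered square and the derivative's mean-centered
#' square, giving 24 motion + 12 physiological = 36 columns. If a
#' framewise-displacement vector is supplied, binary spike regressors are
#' attached (attribute `spikes`) for frames with FD above `fd_threshold`.
#'
#' @param motion Numeric matrix with 6 columns (rotations/translations).
#' @param physio Numeric matrix with 3 columns (global, white-matter,
#'   CSF signals).
#' @param fd Optional framewise-displacement vector (mm).
#' @param fd_threshold Spike threshold in mm (default 0.5).
#' @return 36-column matrix; attributes `spikes` (0/1 matrix, one column
#'   per flagged frame) and `spike_frames` when `fd` is given.
#' @export
expand_confounds <- function(motion, physio, fd = NULL, fd_threshold = 0.5) {
  motion <- as.matrix(motion); physio <- as.matrix(physio)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  if (ncol(physio) != 3) stop("physio must have 3 columns")
  if (nrow(motion) != nrow(physio))
    stop("motion and physio must have the same number of rows")
  expand_block <- function(M, prefix) {
    d <- apply(M, 2, function(x) c(0, diff(x)))
    out <- cbind(apply(M, 2, center),
                 apply(d, 2, center),
                 apply(apply(M, 2, center)^2, 2, center),
                 apply(d^2, 2, center))
    colnames(out) <- paste0(prefix, rep(seq_len(ncol(M)), 4), ".",
                            rep(c("c", "d", "sq", "dsq"), each = ncol(M)))
    out
  }
  X <- cbind(expand_block(motion, "motion"), expand_block(physio, "physio"))
  if (!is.null(fd)) {
    if (length(fd) != nrow(motion))
      stop("fd must have one value per frame")
    spike_frames <- which(fd > fd_threshold)
    spikes <- matrix(0, nrow(motion), length(spike_frames))
    if (length(spike_frames))
      spikes[cbind(spike_frames, seq_along(spike_frames))] <- 1
    colnames(spikes) <- if (length(spike_frames))
      paste0("spike", spike_frames) else character(0)
    attr(X, "spikes") <- spikes
    attr(X, "spike_frames") <- spike_frames
  }
  X
}

#' Precomputed condition regressors and trial windows
#'
#' Computes H_task and the trial windows for each of the six ON/OFF
#' analysis conditions once, so that per-subject statistics can reuse
#' them (the design is identical across subjects).
#'
#' @inheritParams extract_trial_windows
#' @return Named list (C1...W3) of `list(H, windows)`, class
#'   `condition_weights`.
#' @export
condition_weights <- function(design, epsilon = 1e-6, oversample = 16,
                              t_ref = 0.5) {
  out <- lapply(names(condition_codes()), function(cc) {
    list(H = build_condition_regressor(design, cc, oversample, t_ref),
         windows = extract_trial_windows(design, cc, epsilon, oversample,
                                         t_ref))
  })
  names(out) <- names(condition_codes())
  structure(out, class = "condition_weights")
}
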