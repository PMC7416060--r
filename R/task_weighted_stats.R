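# Task-modulated variability statistics. A per-frame measure (a
# pair-averaged connection weight or a topological index) is multiplied
# by the non-mean-centered HRF-convolved condition regressor H_task; the
# per-trial sample SD (divisor T1 - 1) of the weighted values is averaged
# over the condition's trials. Pair averaging over N_Conn happens per
# frame *before* weighting, following the statistic's nesting.

check_windows <- function(trace, H, windows) {
  h <- regressor_values(H)
  if (length(trace) != length(h))
    stop("trace and regressor lengths differ (", length(trace), " vs ",
         length(h), ")")
  for (w in windows) {
    if (!inherits(w, "trial_window")) stop("windows must be trial_window objects")
    if (w$T1 < 2) stop("degenerate window: trial ", w$trial_index,
                       " has T1 < 2")
    if (max(w$frames) > length(trace))
      stop("window frames exceed trace length")
  }
  h
}

#' Task-modulated standard deviation of a per-frame measure
#'
#' For each trial window, the measure trace is weighted frame-by-frame by
#' H_task and the sample standard deviation (divisor T1 - 1) of the
#' weighted values is taken around the trial mean; the statistic is the
#' average of those per-trial SDs over the condition's trials.
#'
#' @param trace Per-frame measure vector (length `n_frames`).
#' @param H The condition's [build_condition_regressor] output (or a bare
#'   numeric vector), not mean-centered.
#' @param windows Trial windows from [extract_trial_windows] for the same
#'   condition.
#' @return Scalar d_SD (>= 0).
#' @export
task_weighted_sd <- function(trace, H, windows) {
  h <- check_windows(trace, H, windows)
  mean(vapply(windows, function(w) stats::sd(trace[w$frames] * h[w$frames]),
              numeric(1)))
}

#' Task-modulated mean of a per-frame measure
#'
#' The per-trial mean of the H_task-weighted measure, averaged over
#' trials. Companion location statistic to [task_weighted_sd()].
#'
#' @inheritParams task_weighted_sd
#' @return Scalar d_mean.
#' @export
task_weighted_mean <- function(trace, H, windows) {
  h <- check_windows(trace, H, windows)
  mean(vapply(windows, function(w) mean(trace[w$frames] * h[w$frames]),
              numeric(1)))
}

#' Task-weighted statistics for all measures and conditions of a subject
#'
#' Computes d_SD and d_mean for each of the 12 connection summaries and
#' (optionally) the three topological indexes, for each of the six
#' ON/OFF conditions. Measures with missing frames inside a window are
#' flagged `NA`.
#'
#' @param summaries A [summarize_series] result (12 x T matrix).
#' @param design The [task_design] the series was acquired under.
#' @param topo Optional [topology_series] data frame for the same frames.
#' @param subject Subject identifier stored in the output.
#' @param weights Optional [condition_weights()] precomputed for
#'   `design`; computed on the fly when `NULL`.
#' @param epsilon,oversample,t_ref Passed to [extract_trial_windows] /
#'   [build_condition_regressor] when `weights` is `NULL`.
#' @return Long data frame: `subject`, `measure`, `measure_class`
#'   (primary/secondary), `condition` (C1...W3), `d_sd`, `d_mean`.
#' @export
stat_table <- function(summaries, design, topo = NULL, subject = "s1",
                       weights = NULL, epsilon = 1e-6, oversample = 16,
                       t_ref = 0.5) {
  stopifnot(inherits(design, "task_design"))
  if (is.null(weights))
    weights <- condition_weights(design, epsilon, oversample, t_ref)
  traces <- lapply(rownames(summaries), function(m) summaries[m, ])
  names(traces) <- rownames(summaries)
  classes <- rep("primary", length(traces))
  if (!is.null(topo)) {
    for (m in c("G_Eff", "G_Mod", "G_Res")) {
      traces[[m]] <- topo[[m]]
      classes <- c(classes, "secondary")
    }
  }
  codes <- condition_codes()
  rows <- list()
  for (cc in names(codes)) {
    H <- weights[[cc]]$H
    windows <- weights[[cc]]$windows
    for (k in seq_along(traces)) {
      tr <- traces[[k]]
      if (anyNA(tr[unlist(lapply(windows, `[[`, "frames"))])) {
        dsd <- NA_real_; dmn <- NA_real_
      } else {
        dsd <- task_weighted_sd(tr, H, windows)
        dmn <- task_weighted_mean(tr, H, windows)
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, measure = names(traces)[k],
        measure_class = classes[k], condition = cc,
        d_sd = dsd, d_mean = dmn, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
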