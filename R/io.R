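# File dialects and the stage-chaining pipeline. All tabular inputs and
# outputs are plain tab-delimited text; the per-frame correlation stacks
# (frames x regions^2 doubles) are written as RDS sidecars next to the
# tables.

#' Read a frames x regions time-series matrix
#'
#' Tab- or comma-delimited numeric file with a header row of region ids.
#' Non-numeric or missing cells are rejected with the offending row and
#' column named.
#'
#' @param path File path.
#' @return Numeric matrix, frames as rows, region ids as column names.
#' @export
read_timeseries <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, comment.char = "#")
  M <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) M <- matrix(M, 1, dimnames = list(NULL, names(df)))
  bad <- which(is.na(M), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric or missing value at row ", bad[1, 1], ", column '",
         colnames(M)[bad[1, 2]], "' of ", path)
  rownames(M) <- NULL
  M
}

#' Write a time-series matrix
#'
#' @param X Numeric matrix with region-id column names.
#' @param path Destination path (tab-delimited).
#' @export
write_timeseries <- function(X, path) {
  utils::write.table(X, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BIDS-style events table
#'
#' Tab-delimited with header columns `onset`, `duration`, `trial_type`;
#' onsets in seconds from the first frame acquisition.
#'
#' @param path File path.
#' @return Data frame suitable for [task_design()].
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", comment.char = "#")
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("events file must have columns onset, duration, trial_type")
  ev[need]
}

#' Read a region-membership table
#'
#' Tab-delimited with columns `region_id` and `network`; labels matched
#' case-insensitively, unknown labels mapped to `other` with a warning.
#'
#' @param path File path.
#' @return A [roi_membership].
#' @export
read_membership <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          colClasses = "character")
  if (!all(c("region_id", "network") %in% names(df)))
    stop("membership file must have columns region_id, network")
  roi_membership(df$region_id, df$network)
}

#' Read a per-frame confounds table
#'
#' @param path Tab-delimited file, one row per frame, named columns.
#' @return Data frame.
#' @export
read_confounds <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_tagged_table <- function(df, path, tag) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", tag), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a synthetic cohort as a study directory
#'
#' Emits exactly the dialects the pipeline reads: `events.tsv`,
#' `membership.tsv`, `covariates.tsv`, per-subject
#' `<id>_timeseries.tsv` and `<id>_confounds.tsv`, and a
#' `manifest.json` listing files, seeds and the ground truth.
#'
#' @param cohort A [simulate_cohort] result.
#' @param dir Destination directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  utils::write.table(cohort$design$events, p("events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$membership, p("membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$covariates, p("covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- list()
  for (su in cohort$subjects) {
    ts <- paste0(su$id, "_timeseries.tsv")
    cf <- paste0(su$id, "_confounds.tsv")
    write_timeseries(su$X, p(ts))
    utils::write.table(su$confounds, p(cf), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[su$id]] <- list(timeseries = ts, confounds = cf,
                           group = su$group, seed = su$seed)
  }
  manifest <- list(TR = cohort$design$TR, n_frames = cohort$design$n_frames,
                   seed = cohort$seed, subjects = files,
                   ground_truth = cohort$ground_truth)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             p("manifest.json"))
  invisible(dir)
}

#' Read a study directory written by [write_cohort()]
#'
#' @param dir Study directory.
#' @return List with `subjects` (id, group, X, confounds), `membership`,
#'   `design`, `covariates`.
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  design <- task_design(read_events(file.path(dir, "events.tsv")),
                        TR = manifest$TR, n_frames = manifest$n_frames)
  membership <- read_membership(file.path(dir, "membership.tsv"))
  covariates <- utils::read.delim(file.path(dir, "covariates.tsv"))
  subjects <- lapply(names(manifest$subjects), function(id) {
    info <- manifest$subjects[[id]]
    ts_path <- file.path(dir, info$timeseries)
    if (!file.exists(ts_path))
      stop("missing time-series file for subject ", id, ": ", ts_path)
    list(id = id, group = info$group, X = read_timeseries(ts_path),
         confounds = read_confounds(file.path(dir, info$confounds)))
  })
  list(subjects = subjects, membership = membership, design = design,
       covariates = covariates)
}

#' Pipeline configuration
#'
#' Validated flat key-value options for [run_pipeline()]. Unknown keys
#' are rejected.
#'
#' @param ... Named options among: `topology` (logical; compute the
#'   per-frame topological indexes, default `FALSE`), `exact_max`
#'   (modularity exact-optimum size cap, default 16), `q_max`, `p_max`
#'   (restricted-FDR parameters, defaults 0.25 / 0.050), `reltol`
#'   (estimator tolerance, default 1e-7), `user_group` (default
#'   `"CAN"`), `craving` (craving score columns, default
#'   `c("craving_prescan", "craving_duringscan")`).
#' @return List of class `study_config`.
#' @export
study_config <- function(...) {
  defaults <- list(topology = FALSE, exact_max = 16, q_max = 0.25,
                   p_max = 0.050, reltol = 1e-7, user_group = "CAN",
                   craving = c("craving_prescan", "craving_duringscan"))
  opts <- list(...)
  unknown <- setdiff(names(opts), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, opts)
  if (cfg$q_max <= 0 || cfg$q_max > 1) stop("q_max must be in (0, 1]")
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop("p_max must be in (0, 1]")
  structure(cfg, class = "study_config")
}

#' Run the full analysis pipeline
#'
#' Chains the stages over a cohort: per subject, dynamic conditional
#' correlations, connection summaries, (optionally) topological indexes,
#' and the task-weighted statistic table; then the group layer:
#' repeated-measures ANOVA for the primary (and, with topology, the
#' secondary) family and the craving correlation grid. A stage failure
#' aborts with the stage and subject named.
#'
#' @param input A [simulate_cohort] result or a study directory path
#'   from [write_cohort()].
#' @param config A [study_config()].
#' @param out_dir Optional output directory; per-stage tables are
#'   written there, tagged with the config hash and seed.
#' @param seed Seed recorded in outputs (the pipeline itself is
#'   deterministic given its input).
#' @return List of class `pipeline_result`: `stats` (stacked
#'   [stat_table()] rows), `fits` (per-subject estimator diagnostics),
#'   `anova_primary`, `anova_secondary` (or `NULL`), `craving_primary`,
#'   `craving_secondary` (or `NULL`), `covariates`, `config`.
#' @export
run_pipeline <- function(input, config = study_config(), out_dir = NULL,
                         seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  study <- if (inherits(input, "synthetic_cohort")) input else
    read_study(input)
  subjects <- study$subjects
  membership <- study$membership
  design <- study$design

  weights <- condition_weights(design)
  stats_rows <- list()
  fits <- list()
  stacks <- list()
  for (su in subjects) {
    res <- tryCatch({
      fit <- dcc_series(su$X, reltol = config$reltol)
      summ <- summarize_series(fit, membership)
      topo <- if (config$topology)
        topology_series(fit, exact_max = config$exact_max) else NULL
      tab <- stat_table(summ, design, topo = topo, subject = su$id,
                        weights = weights)
      list(fit = fit, tab = tab)
    }, error = function(e) e)
    if (inherits(res, "error"))
      stop("pipeline stage failed for subject ", su$id, ": ",
           conditionMessage(res))
    stats_rows[[su$id]] <- res$tab
    fits[[su$id]] <- list(garch = res$fit$garch, dcc = res$fit$dcc[
      c("a", "b", "log_likelihood", "converged")])
    if (!is.null(out_dir)) stacks[[su$id]] <- res$fit$R
  }
  stat_tbl <- do.call(rbind, stats_rows)
  rownames(stat_tbl) <- NULL

  covariates <- study$covariates
  anova_primary <- rm_anova(stat_tbl, covariates, family = "primary")
  anova_secondary <- if (config$topology)
    rm_anova(stat_tbl, covariates, family = "secondary") else NULL
  craving <- intersect(config$craving, names(covariates))
  craving_primary <- if (length(craving))
    craving_correlations(stat_tbl, covariates, craving,
                         user_group = config$user_group,
                         family = "primary", q_max = config$q_max,
                         p_max = config$p_max) else NULL
  craving_secondary <- if (length(craving) && config$topology)
    craving_correlations(stat_tbl, covariates, craving,
                         user_group = config$user_group,
                         family = "secondary", q_max = config$q_max,
                         p_max = config$p_max) else NULL

  out <- structure(list(stats = stat_tbl, fits = fits,
                        anova_primary = anova_primary,
                        anova_secondary = anova_secondary,
                        craving_primary = craving_primary,
                        craving_secondary = craving_secondary,
                        covariates = covariates, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- paste0("dynconn config=", config_hash(unclass(config)),
                  " seed=", if (is.null(seed)) "NA" else seed)
    write_tagged_table(stat_tbl, file.path(out_dir, "task_stats.tsv"), tag)
    write_tagged_table(anova_primary$per_measure,
                       file.path(out_dir, "anova_primary.tsv"), tag)
    if (!is.null(anova_secondary))
      write_tagged_table(anova_secondary$per_measure,
                         file.path(out_dir, "anova_secondary.tsv"), tag)
    if (!is.null(craving_primary))
      write_tagged_table(craving_primary,
                         file.path(out_dir, "craving_primary.tsv"), tag)
    if (!is.null(craving_secondary))
      write_tagged_table(craving_secondary,
                         file.path(out_dir, "craving_secondary.tsv"), tag)
    saveRDS(stacks, file.path(out_dir, "correlation_stacks.rds"))
    writeLines(jsonlite::toJSON(
      list(config = unclass(config), seed = seed,
           fits = lapply(fits, function(f) f$dcc)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(out_dir, "fit_report.json"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$fits), "subjects,",
      length(unique(x$stats$measure)), "measures x 6 conditions\n")
  invisible(x)
}
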