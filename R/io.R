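# File formats and the end-to-end pipeline.

.participant_cols <- c("participant_id", "lab", "collection_order",
                       "n_trials", "negative_count")

#' Read and validate a participant CSV
#'
#' Reads the participant schema
#' `participant_id,lab,collection_order,n_trials,negative_count`, validates
#' every row (counts within `0..n_trials`, unique collection order), and
#' returns the records sorted by `collection_order`.
#'
#' @param path Path to a CSV file with the documented header.
#' @return Participant tibble sorted by `collection_order`.
#' @export
read_participants <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.participant_cols, names(raw))
  if (length(missing)) {
    abort(sprintf("participant file is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  validate_participants(raw, source = path)
}

#' Validate a participant table
#'
#' Row-level validation used by [read_participants()]: counts must lie in
#' `0..n_trials` and `collection_order` must be unique positive integers.
#' Errors name the first offending row.
#'
#' @param cohort Participant data frame.
#' @param source Label used in error messages.
#' @return The validated tibble sorted by `collection_order`.
#' @export
validate_participants <- function(cohort, source = "participant data") {
  cohort <- as_tibble(cohort)
  bad <- which(!is.finite(cohort$negative_count) |
                 cohort$negative_count < 0 |
                 cohort$negative_count > cohort$n_trials)
  if (length(bad)) {
    abort(sprintf(
      "%s: row %d has negative_count = %s outside 0..n_trials = %s.",
      source, bad[1L], format(cohort$negative_count[bad[1L]]),
      format(cohort$n_trials[bad[1L]])))
  }
  if (any(!is.finite(cohort$collection_order) | cohort$collection_order < 1)) {
    abort(sprintf("%s: `collection_order` must be positive integers.", source))
  }
  dup <- which(duplicated(cohort$collection_order))
  if (length(dup)) {
    abort(sprintf("%s: row %d duplicates collection_order = %s.",
                  source, dup[1L], format(cohort$collection_order[dup[1L]])))
  }
  dplyr::arrange(cohort, .data$collection_order)
}

#' Write a participant CSV
#'
#' @param cohort Participant tibble (see [simulate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(cohort, path) {
  readr::write_csv(cohort[, .participant_cols], path, progress = FALSE)
  invisible(path)
}

#' Write a sequential-curve CSV
#'
#' Writes the trajectory with columns
#' `cumulative_n,mean,sd,t,bf10,bf01`.
#'
#' @param curve A [sequential_bf()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "seqbf_curve"))
  readr::write_csv(curve$data, path, progress = FALSE)
  invisible(path)
}

#' Read a sequential-curve CSV
#'
#' @param path Path written by [write_curve()].
#' @param config The [bf_config()] the curve was computed under.
#' @return A `seqbf_curve` object.
#' @export
read_curve <- function(path, config = bf_config()) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cumulative_n", "bf10")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(sprintf("curve file is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  structure(list(data = data, config = config), class = "seqbf_curve")
}

#' End-to-end replication analysis
#'
#' Chains all analysis stages on one ordered cohort: the sequential
#' Bayes-factor trajectory with stopping evaluation, the prior-robustness
#' sweep, per-lab Bayes factors with the random-effects meta-analysis (when
#' the cohort has at least two labs), and the temporal-anomaly statistics
#' calibrated against a fresh Monte Carlo null distribution.  The whole run
#' is deterministic given the inputs and `seed`.
#'
#' @param cohort Participant tibble (e.g. [simulate_cohort()] or
#'   [read_participants()]), already ordered by `collection_order`.
#' @param config A [bf_config()].
#' @param prior_scales Grid for the robustness sweep.
#' @param n_sims Number of null simulations for the anomaly calibration
#'   (>= 1).
#' @param seed Master seed for the null simulations.
#' @param scaling FFT normalization (see [amplitude_spectrum()]).
#' @param out_dir Optional directory; when given, writes `curve.csv`,
#'   `robustness.csv`, `labs.csv`, `meta.json`, `null_distribution.csv`, and
#'   `summary.json` into it.
#' @param progress Forwarded to [build_null()].
#' @return A list of class `seqbf_report` with elements `summary` (one-row
#'   tibble), `curve`, `stopping`, `robustness`, `labs`, `meta`, `anomaly`,
#'   and `null`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(labs = c(A = 150, B = 100), seed = 8)
#' rep <- run_replication_analysis(cohort, n_sims = 5, seed = 8)
#' rep$summary
#' }
#' @export
run_replication_analysis <- function(cohort, config = bf_config(),
                                     prior_scales = c(0.1, 0.707, 1, 1.414),
                                     n_sims = 1000, seed = 1,
                                     scaling = c("half", "amplitude"),
                                     out_dir = NULL, progress = FALSE) {
  scaling <- match.arg(scaling)
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L) abort("`n_sims` must be an integer >= 1.")
  cohort <- validate_participants(cohort, source = "cohort")

  curve <- sequential_bf(cohort, config)
  stopping <- stopping_check(curve, threshold = config$stop_bf)
  overall <- summarize_counts(cohort$negative_count, mu0 = config$mu0)
  robust <- robustness_sweep(overall, prior_scales = prior_scales,
                             direction = config$direction, mu0 = config$mu0)

  labs <- meta <- NULL
  if ("lab" %in% names(cohort) && length(unique(cohort$lab)) >= 2L) {
    labs <- lab_bayes_factors(lab_summaries(cohort), config)
    meta <- meta_random_effects(labs, mu0 = config$mu0)
  }

  null <- build_null(n_sims = n_sims, n_participants = nrow(cohort),
                     n_trials = cohort$n_trials[1L], config = config,
                     seed = seed, scaling = scaling, progress = progress)
  anomaly <- anomaly_test(curve, null)

  n <- nrow(cohort)
  summary <- tibble(
    n = n, mean = overall$mean, sd = overall$sd, t = overall$t,
    final_bf10 = curve$data$bf10[n], final_bf01 = curve$data$bf01[n],
    decision = stopping$decision, n_stop = stopping$n_stop,
    max_bf = anomaly$max_bf, max_at_n = anomaly$max_at_n,
    energy = anomaly$energy, amp_sum = anomaly$amp_sum,
    p_max_bf = anomaly$p_max_bf, p_energy = anomaly$p_energy,
    p_amp_sum = anomaly$p_amp_sum, p_combined = anomaly$p_combined,
    n_sims = n_sims, seed = as.integer(seed))

  report <- structure(
    list(summary = summary, curve = curve, stopping = stopping,
         robustness = robust, labs = labs, meta = meta,
         anomaly = anomaly, null = null),
    class = "seqbf_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.seqbf_report <- function(x, ...) {
  s <- x$summary
  cat("<seqbf_report>\n")
  cat(sprintf("  n = %d, mean = %.3f, sd = %.3f, t = %.3f\n",
              s$n, s$mean, s$sd, s$t))
  cat(sprintf("  final BF10 = %.4g (BF01 = %.4g); stopping: %s\n",
              s$final_bf10, s$final_bf01, s$decision))
  cat(sprintf("  anomaly: max BF %.4g at n = %d (p = %.4g), energy %.6g (p = %.4g), amp_sum %.4g (p = %.4g)\n",
              s$max_bf, s$max_at_n, s$p_max_bf, s$energy, s$p_energy,
              s$amp_sum, s$p_amp_sum))
  invisible(x)
}

#' Write all report artifacts of a pipeline run
#'
#' @param report A [run_replication_analysis()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "seqbf_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_curve(report$curve, file.path(out_dir, "curve.csv"))
  readr::write_csv(report$robustness, file.path(out_dir, "robustness.csv"),
                   progress = FALSE)
  if (!is.null(report$labs)) {
    readr::write_csv(report$labs, file.path(out_dir, "labs.csv"), progress = FALSE)
    jsonlite::write_json(as.list(glance(report$meta)),
                         file.path(out_dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  readr::write_csv(report$null$stats,
                   file.path(out_dir, "null_distribution.csv"), progress = FALSE)
  jsonlite::write_json(as.list(report$summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
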