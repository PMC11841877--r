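# End-to-end orchestration: cohort (+ optional accelerometry) -> ensemble ->
# codebook clustering -> participant labels -> summaries and statistics.

#' Run the full profiling pipeline
#'
#' Stages, in order: optional accelerometer preprocessing (mean daily MVPA
#' merged into the cohort), SOM ensemble training with selection by the
#' product of quantization and topographic errors, k-means on the selected
#' codebook with Davies-Bouldin choice of k, propagation of cluster labels to
#' participants, per-cluster median/IQR summaries, component-plane export and
#' the nonparametric statistics report. A manifest records the seed, stage
#' parameters and input hashes so a run can be reproduced exactly.
#'
#' @param cohort Cohort data.frame (e.g. from [generate_cohort()]).
#' @param counts Optional [count_series()]; when supplied, mean daily MVPA is
#'   computed with [process_counts()] and overwrites `daily_mvpa` for valid
#'   participants (invalid participants are dropped with a warning).
#' @param variables Input variables to train on.
#' @param spec An [ensemble_spec()]; its seed is overridden by `seed`.
#' @param grid `NULL` for automatic sizing or a [som_grid()].
#' @param k_range,restarts Codebook clustering controls.
#' @param alpha Significance level for the report.
#' @param seed Master seed for the run.
#' @param out_dir Optional directory: writes cohort, ensemble trace, codebook,
#'   Davies-Bouldin trace, labels, component planes, cluster summary and the
#'   manifest as CSV/JSON.
#' @return `profile_pipeline` result: `cohort`, `ensemble`, `som`,
#'   `solution`, `summary`, `planes`, `report`, `manifest`.
#' @export
run_pipeline <- function(cohort, counts = NULL,
                         variables = input_variables()$variable,
                         spec = ensemble_spec(), grid = NULL,
                         k_range = 2:10, restarts = 100L, alpha = 0.05,
                         seed = 1L, out_dir = NULL) {
  spec$seed <- as.integer(seed)
  if (!is.null(counts)) {
    acc <- process_counts(counts)
    mvpa <- acc$participants
    drop <- cohort$participant_id %in% mvpa$participant_id[!mvpa$valid]
    if (any(drop)) {
      warning(sprintf("%d participant(s) excluded by the wear-time criterion",
                      sum(drop)))
      cohort <- cohort[!drop, , drop = FALSE]
    }
    idx <- match(cohort$participant_id, mvpa$participant_id)
    has <- !is.na(idx)
    cohort$daily_mvpa[has] <- mvpa$mean_daily_mvpa[idx[has]]
  }
  x <- cohort_matrix(cohort, variables)
  ens <- run_ensemble(x, spec, grid = grid)
  som <- select_best(ens)
  sol <- choose_k(som$codebook, k_range = k_range, restarts = restarts,
                  seed = seed)
  sol <- assign_participants(som, sol, x)
  summ <- cluster_summary(cohort, sol, variables)
  planes <- export_component_planes(som)
  report <- profile_report(cohort, sol, input_vars = variables, alpha = alpha)
  manifest <- list(
    seed = seed, n = nrow(cohort), variables = variables,
    grid = c(som$grid$height, som$grid$width),
    ensemble = list(repeats = spec$repeats, modes = spec$modes,
                    kinds = spec$kinds, inits = spec$inits),
    k_range = range(k_range), restarts = restarts, alpha = alpha,
    chosen_k = sol$k, best_run = ens$best_run,
    cohort_md5 = object_md5(cohort),
    counts_md5 = if (is.null(counts)) NULL else object_md5(as.data.frame(counts)),
    package_version = as.character(utils::packageVersion("somprofiler"))
  )
  result <- structure(
    list(cohort = cohort, ensemble = ens, som = som, solution = sol,
         summary = summ, planes = planes, report = report,
         manifest = manifest),
    class = "profile_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.profile_pipeline <- function(x, ...) {
  cat(sprintf("<profile_pipeline> n = %d | %d x %d map | k = %d clusters\n",
              nrow(x$cohort), x$som$grid$height, x$som$grid$width,
              x$solution$k))
  print(x$ensemble)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' @param result A `profile_pipeline`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(result$cohort, p("cohort.csv"), row.names = FALSE)
  utils::write.csv(result$ensemble$trace, p("ensemble_trace.csv"),
                   row.names = FALSE)
  cb <- as.data.frame(result$som$codebook)
  cb <- cbind(row = rep(seq_len(result$som$grid$height),
                        each = result$som$grid$width),
              col = rep(seq_len(result$som$grid$width),
                        times = result$som$grid$height), cb)
  utils::write.csv(cb, p("codebook.csv"), row.names = FALSE)
  utils::write.csv(result$solution$db_trace, p("db_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(participant_id = result$cohort$participant_id,
               cluster = result$solution$participant_labels),
    p("participant_labels.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(neuron = seq_along(result$solution$neuron_labels),
               cluster = result$solution$neuron_labels,
               hits = result$solution$hits),
    p("neuron_labels.csv"), row.names = FALSE)
  utils::write.csv(result$summary, p("cluster_summary.csv"),
                   row.names = FALSE)
  for (v in names(result$planes)) {
    utils::write.csv(result$planes[[v]],
                     p(sprintf("plane_%s.csv", v)), row.names = FALSE)
  }
  utils::write.csv(result$report$input_tests, p("input_tests.csv"),
                   row.names = FALSE)
  if (!is.null(result$report$outcome_tests)) {
    utils::write.csv(result$report$outcome_tests, p("outcome_tests.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write / read a cohort as CSV
#'
#' One row per participant; columns are `participant_id`, the input
#' variables, any outcome columns, `gender` and (for synthetic cohorts)
#' `true_profile`.
#'
#' @param cohort Cohort data.frame.
#' @param path CSV path.
#' @return `path` (write) or the cohort data.frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$gender)) df$gender <- factor(df$gender,
                                               levels = c("girl", "boy"))
  df
}

#' Write / read a count series as CSV
#'
#' Columns: `participant_id`, `day`, `day_type`, `epoch`, `counts`; the epoch
#' length is stored in a leading comment line.
#'
#' @param series A [count_series()].
#' @param path CSV path.
#' @return `path` (write) or a `count_series` (read).
#' @export
write_counts_csv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epoch_seconds=%d", attr(series, "epoch_seconds")), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  first <- readLines(path, n = 1)
  epoch <- if (grepl("^# epoch_seconds=", first)) {
    as.integer(sub("^# epoch_seconds=", "", first))
  } else 60L
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  count_series(df, epoch)
}
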