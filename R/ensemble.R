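# Ensemble of SOM configurations, selected by the product of quantization
# and topographic errors.

#' Specify a SOM ensemble
#'
#' The full configuration grid is every combination of training mode,
#' neighborhood kernel and initialization, each repeated `repeats` times with
#' a distinct derived seed (`run seed = base seed + run index`), for
#' `repeats * |modes| * |kinds| * |inits|` runs in total. The study-scale
#' grid (100 repeats, both modes, all four kernels, both initializations)
#' yields 1600 maps.
#'
#' @param repeats Repetitions per configuration (>= 1).
#' @param modes Subset of `c("sequential", "batch")`.
#' @param kinds Subset of the four neighborhood kernels.
#' @param inits Subset of `c("random", "linear")`.
#' @param seed Base seed.
#' @return An `ensemble_spec` object.
#' @export
ensemble_spec <- function(repeats = 100L,
                          modes = c("sequential", "batch"),
                          kinds = c("gaussian", "bubble", "cutgauss", "ep"),
                          inits = c("random", "linear"),
                          seed = 1L) {
  stopifnot(repeats >= 1, length(modes) >= 1, length(kinds) >= 1,
            length(inits) >= 1)
  modes <- match.arg(modes, c("sequential", "batch"), several.ok = TRUE)
  kinds <- match.arg(kinds, .som_kinds, several.ok = TRUE)
  inits <- match.arg(inits, c("random", "linear"), several.ok = TRUE)
  structure(list(repeats = as.integer(repeats), modes = modes, kinds = kinds,
                 inits = inits, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> %d x %d x %d x %d = %d runs (base seed %d)\n",
              x$repeats, length(x$modes), length(x$kinds), length(x$inits),
              x$repeats * length(x$modes) * length(x$kinds) * length(x$inits),
              x$seed))
  invisible(x)
}

#' Train the full SOM ensemble
#'
#' Trains one map per (repeat, mode, kernel, initialization) combination,
#' records quantization error, topographic error and their product for every
#' run, and keeps the best map. A failing run is recorded with its error
#' message and excluded from selection (with a warning).
#'
#' @param x Native-scale data matrix (cases x variables).
#' @param spec An [ensemble_spec()].
#' @param grid Optional [som_grid()]; `NULL` sizes the map from the data.
#' @param standardize Passed to [som_fit()].
#' @param schedule Optional shared training schedule.
#' @return `som_ensemble`: `trace` (data.frame run_id, mode, kernel, init,
#'   seed, qe, te, score, status), `best` (the winning `trained_som`),
#'   `best_run` (its run_id), `spec`.
#' @export
run_ensemble <- function(x, spec = ensemble_spec(), grid = NULL,
                         standardize = TRUE, schedule = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  x <- as.matrix(x)
  if (is.null(grid)) {
    z <- scale(x)
    z[, apply(x, 2, stats::sd) == 0] <- 0
    hw <- map_size(nrow(x), eig_ratio(if (standardize) z else x))
    grid <- som_grid(hw[1], hw[2])
  }
  combos <- expand.grid(rep = seq_len(spec$repeats), mode = spec$modes,
                        kind = spec$kinds, init = spec$inits,
                        stringsAsFactors = FALSE)
  n_runs <- nrow(combos)
  trace <- data.frame(run_id = seq_len(n_runs), mode = combos$mode,
                      kernel = combos$kind, init = combos$init,
                      seed = spec$seed + seq_len(n_runs),
                      qe = NA_real_, te = NA_real_, score = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
  best <- NULL
  best_key <- c(Inf, Inf, Inf)  # score, qe, run order
  for (i in seq_len(n_runs)) {
    fit <- tryCatch(
      som_fit(x, grid = grid, mode = combos$mode[i], kind = combos$kind[i],
              init = combos$init[i], seed = trace$seed[i],
              schedule = schedule, standardize = standardize),
      error = function(e) e)
    if (inherits(fit, "error")) {
      trace$status[i] <- paste("failed:", conditionMessage(fit))
      warning(sprintf("ensemble run %d failed: %s", i, conditionMessage(fit)),
              call. = FALSE)
      next
    }
    trace$qe[i] <- fit$qe
    trace$te[i] <- fit$te
    trace$score[i] <- fit$qe * fit$te
    key <- c(trace$score[i], fit$qe, i)
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best_key <- key
      best <- fit
      best_run <- i
    }
  }
  if (is.null(best)) stopf("all ensemble runs failed")
  structure(list(trace = trace, best = best, best_run = best_run,
                 spec = spec),
            class = "som_ensemble")
}

#' Select the best map from an ensemble trace
#'
#' Minimizes the product of quantization and topographic errors over
#' successful runs; ties are broken by lower quantization error, then by run
#' order (so a zero topographic error, whose product carries no ordering
#' information, falls back to map fit).
#'
#' @param ensemble A `som_ensemble` (returns its stored best map) or the
#'   trace data.frame alone (returns the winning run_id).
#' @return The best `trained_som`, or the winning run_id when given a trace.
#' @export
select_best <- function(ensemble) {
  trace <- if (inherits(ensemble, "som_ensemble")) ensemble$trace else ensemble
  ok <- trace[trace$status == "ok" & !is.na(trace$score), , drop = FALSE]
  if (!nrow(ok)) stopf("no successful ensemble runs to select from")
  ord <- order(ok$score, ok$qe, ok$run_id)
  win <- ok$run_id[ord[1]]
  if (inherits(ensemble, "som_ensemble")) {
    stopifnot(win == ensemble$best_run)
    ensemble$best
  } else {
    win
  }
}

#' @export
print.som_ensemble <- function(x, ...) {
  ok <- sum(x$trace$status == "ok")
  cat(sprintf("<som_ensemble> %d runs (%d ok) | best run %d: %s/%s/%s, %s\n",
              nrow(x$trace), ok, x$best_run,
              x$trace$mode[x$best_run], x$trace$kernel[x$best_run],
              x$trace$init[x$best_run],
              sprintf("QE %.4f x TE %.4f = %.5f", x$best$qe, x$best$te,
                      x$best$qe * x$best$te)))
  invisible(x)
}
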