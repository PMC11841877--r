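# Synthetic cohort generation: median-matched truncated normal draws.

# Median of a normal(mu, sigma) truncated to [lower, upper].
.truncnorm_median <- function(mu, sigma, lower, upper) {
  pa <- pnorm((lower - mu) / sigma)
  pb <- pnorm((upper - mu) / sigma)
  mu + sigma * qnorm((pa + pb) / 2)
}

# Pre-truncation mean such that the truncated distribution has median
# `location`. Solved numerically; when `location` sits on (or hugs) a bound
# the solution is capped at location +/- 8 sigma, which places the realized
# median just inside the bound.
.truncnorm_center <- function(location, sigma, lower, upper) {
  f <- function(mu) .truncnorm_median(mu, sigma, lower, upper) - location
  lo <- location - 8 * sigma
  hi <- location + 8 * sigma
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0) return(lo)
  if (fhi < 0) return(hi)
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

# n draws from the median-matched truncated normal via inverse-CDF sampling.
rtrunc_median <- function(n, location, iqr, lower = -Inf, upper = Inf) {
  if (iqr <= 0) return(rep(location, n))
  sigma <- iqr / 1.349
  mu <- .truncnorm_center(location, sigma, lower, upper)
  pa <- pnorm((lower - mu) / sigma)
  pb <- pnorm((upper - mu) / sigma)
  u <- runif(n, pa, pb)
  x <- mu + sigma * qnorm(u)
  pmin(pmax(x, lower), upper)
}

#' Generate a synthetic participant cohort
#'
#' Draws one row per participant from a mixture of latent profiles. Each
#' input variable is sampled from a truncated normal on its admissible
#' interval with the profile's median as the distribution median and
#' `sigma = IQR / 1.349` before truncation; gender is Bernoulli with the
#' profile's girl fraction. The generative profile label is recorded in
#' `true_profile` so downstream cluster-recovery can be scored.
#'
#' @param specs List of [profile_spec()] objects (e.g.
#'   [reference_profiles()]).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param snap_likert If `TRUE`, questionnaire variables with a declared
#'   instrument step are rounded to that grid. Off by default: the map is
#'   trained on continuous scores and several reference medians do not sit on
#'   the instrument grid.
#' @return Data.frame with `participant_id`, the input variables, `gender`
#'   (factor girl/boy) and `true_profile`.
#' @export
generate_cohort <- function(specs, seed = 1L, snap_likert = FALSE) {
  if (!length(specs)) stopf("at least one profile_spec is required")
  if (!all(vapply(specs, inherits, TRUE, "profile_spec"))) {
    stopf("specs must be a list of profile_spec objects")
  }
  sizes <- vapply(specs, function(s) s$size, 1L)
  if (sum(sizes) <= 0) stopf("profile sizes must sum to a positive count")
  vars <- names(specs[[1]]$location)
  iv <- input_variables()
  with_seed(seed, {
    blocks <- lapply(specs, function(sp) {
      n <- sp$size
      cols <- lapply(vars, function(v) {
        b <- sp$bounds[sp$bounds$variable == v, ]
        x <- rtrunc_median(n, sp$location[[v]], sp$spread[[v]],
                           b$lower, b$upper)
        if (snap_likert) {
          step <- iv$step[match(v, iv$variable)]
          if (!is.na(step)) {
            lo <- iv$lower[match(v, iv$variable)]
            x <- lo + round((x - lo) / step) * step
          }
        }
        x
      })
      names(cols) <- vars
      df <- as.data.frame(cols)
      df$gender <- factor(ifelse(runif(n) < sp$girl_fraction, "girl", "boy"),
                          levels = c("girl", "boy"))
      df$true_profile <- rep(sp$name, n)
      df
    })
    out <- do.call(rbind, blocks)
    out <- cbind(participant_id = sprintf("P%04d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Append synthetic cognitive outcomes to a cohort
#'
#' Outcome columns are drawn with the same median-matched truncated-normal
#' scheme as [generate_cohort()], per the participant's `true_profile`;
#' integer-valued outcomes (math fluency, Digit Span, Stroop responses) are
#' rounded to the nearest admissible integer.
#'
#' @param cohort Data.frame from [generate_cohort()] (must carry
#'   `true_profile`).
#' @param outcome_specs Named list of per-profile data.frames with columns
#'   `variable`, `location`, `spread`; defaults to
#'   [reference_outcome_specs()].
#' @param seed Integer seed.
#' @return The cohort with outcome columns appended.
#' @export
generate_outcomes <- function(cohort, outcome_specs = reference_outcome_specs(),
                              seed = 1L) {
  if (is.null(cohort$true_profile)) {
    stopf("cohort lacks true_profile labels; outcomes are drawn per profile")
  }
  unknown <- setdiff(unique(cohort$true_profile), names(outcome_specs))
  if (length(unknown)) {
    stopf("no outcome spec for profile(s): %s", paste(unknown, collapse = ", "))
  }
  ov <- outcome_variables()
  with_seed(seed, {
    n <- nrow(cohort)
    for (v in unique(unlist(lapply(outcome_specs, `[[`, "variable")))) {
      col <- numeric(n)
      lo <- ov$lower[match(v, ov$variable)] %||% -Inf
      hi <- ov$upper[match(v, ov$variable)] %||% Inf
      if (is.na(lo)) { lo <- -Inf; hi <- Inf }
      for (pf in names(outcome_specs)) {
        idx <- which(cohort$true_profile == pf)
        if (!length(idx)) next
        row <- outcome_specs[[pf]]
        r <- row[row$variable == v, ]
        if (!nrow(r)) stopf("profile '%s' has no spec for outcome '%s'", pf, v)
        col[idx] <- rtrunc_median(length(idx), r$location, r$spread, lo, hi)
      }
      isint <- ov$integer[match(v, ov$variable)]
      if (!is.na(isint) && isint) col <- round(col)
      cohort[[v]] <- col
    }
    cohort
  })
}

#' Extract the input-variable matrix from a cohort
#'
#' @param cohort Cohort data.frame.
#' @param variables Character vector of columns; defaults to the fifteen
#'   canonical input variables.
#' @return Numeric matrix (participants x variables) with participant ids as
#'   row names. Rows with any missing input are rejected with an error.
#' @export
cohort_matrix <- function(cohort, variables = input_variables()$variable) {
  missing_cols <- setdiff(variables, names(cohort))
  if (length(missing_cols)) {
    stopf("cohort lacks input column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(cohort[, variables, drop = FALSE])
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0)
    stopf("missing input values in %d row(s) (first: %d); incomplete cases %s",
          length(bad), bad[1], "must be excluded before analysis")
  }
  storage.mode(x) <- "double"
  rownames(x) <- cohort$participant_id
  x
}
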