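# Nonparametric cluster comparisons: Kruskal-Wallis with epsilon-squared,
# Dunn-Bonferroni pairwise tests, chi-square gender association, Stroop
# efficacy ratios, and the noncentral-F ANOVA power utility.

#' Kruskal-Wallis test with epsilon-squared effect size
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) with the
#' chi-square approximation for p and the epsilon-squared effect size
#' `H / (n - 1)`. When all values are identical the statistic is defined as
#' 0 with p = 1.
#'
#' @param values Numeric vector.
#' @param labels Group labels, >= 2 non-empty groups.
#' @return List of class `kw_result`: `H`, `df`, `p`, `epsilon_squared`, `n`.
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stopf("need at least 2 groups")
  if (any(table(labels) == 0)) stopf("empty group in labels")
  if (length(values) < 3) stopf("need at least 3 observations")
  if (length(unique(values)) == 1) {
    out <- list(H = 0, df = nlevels(labels) - 1L, p = 1,
                epsilon_squared = 0, n = length(values))
  } else {
    kt <- stats::kruskal.test(values, labels)
    out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value,
                epsilon_squared = unname(kt$statistic) / (length(values) - 1),
                n = length(values))
  }
  structure(out, class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.3f, p = %.4g, eps^2 = %.4f (n = %d)\n",
              x$df, x$H, x$p, x$epsilon_squared, x$n))
  invisible(x)
}

#' Epsilon-squared effect size for Kruskal-Wallis
#'
#' `eps^2 = H / (n - 1)`: the rank-based share of total variability
#' attributable to group membership.
#'
#' @param H Kruskal-Wallis statistic (>= 0).
#' @param n Total sample size (>= 2).
#' @return Effect size in `[0, 1]`.
#' @export
epsilon_squared <- function(H, n) {
  stopifnot(all(H >= 0), all(n >= 2))
  H / (n - 1)
}

#' Dunn's pairwise tests with Bonferroni correction
#'
#' For each pair of groups, `z = (Rbar_i - Rbar_j) / sqrt(sigma2 * (1/n_i +
#' 1/n_j))` with `sigma2 = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))` (mid-rank
#' tie correction); two-sided p from the standard normal, multiplied by the
#' number of pairs `k(k-1)/2` and capped at 1.
#'
#' @param values Numeric vector.
#' @param labels Group labels.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return Data.frame: `group_i`, `group_j`, `z`, `p`, `p_adjusted`,
#'   `significant`.
#' @export
dunn_bonferroni <- function(values, labels, alpha = 0.05) {
  labels <- factor(labels)
  k <- nlevels(labels)
  if (k < 2) stopf("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes == 0)) stopf("empty group in labels")
  n <- length(values)
  rk <- rank(values)  # mid-ranks
  mean_ranks <- tapply(rk, labels, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(levels(labels), 2)
  n_pairs <- ncol(pairs)
  z <- p <- numeric(n_pairs)
  for (q in seq_len(n_pairs)) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt(sigma2 * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z[q] <- if (se > 0) (mean_ranks[[i]] - mean_ranks[[j]]) / se else 0
    p[q] <- 2 * stats::pnorm(-abs(z[q]))
  }
  p_adj <- pmin(p * n_pairs, 1)
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], z = z, p = p,
             p_adjusted = p_adj, significant = p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Chi-square test of independence
#'
#' Pearson chi-square on a contingency table without continuity correction;
#' errors on zero margins.
#'
#' @param tab Contingency table (matrix or table), at least 2 x 2.
#' @return List of class `chisq_result`: `table`, `statistic`, `df`, `p`,
#'   `expected`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("need at least a 2 x 2 table")
  if (any(tab < 0)) stopf("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("zero margin in contingency table")
  }
  # small-expected-count caveats are left to the caller: the expected counts
  # are returned rather than re-warned on every pipeline run
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 expected = ct$expected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Chi-square independence: X^2(%d) = %.3f, p = %.4g\n",
              x$df, x$statistic, x$p))
  invisible(x)
}

#' Stroop efficacy ratios
#'
#' Interference ratios from the three Stroop rounds: color-word time over dot
#' time, color-word time over neutral-word time, and the same two ratios on
#' total responses. Zero denominators yield `NA` with a warning.
#'
#' @param dot_time,word_time,color_time Completion times (s) per round.
#' @param dot_resp,word_resp,color_resp Total responses per round.
#' @return Data.frame: `dot_time_efficacy`, `word_time_efficacy`,
#'   `dot_responses_efficacy`, `word_responses_efficacy`.
#' @export
stroop_derived <- function(dot_time, word_time, color_time,
                           dot_resp, word_resp, color_resp) {
  ratio <- function(num, den, what) {
    bad <- !is.na(den) & den == 0
    if (any(bad)) {
      warning(sprintf("zero denominator in %s for %d case(s); returning NA",
                      what, sum(bad)))
      den[bad] <- NA
    }
    num / den
  }
  data.frame(
    dot_time_efficacy = ratio(color_time, dot_time, "dot time efficacy"),
    word_time_efficacy = ratio(color_time, word_time, "word time efficacy"),
    dot_responses_efficacy = ratio(color_resp, dot_resp,
                                   "dot responses efficacy"),
    word_responses_efficacy = ratio(color_resp, word_resp,
                                    "word responses efficacy")
  )
}

#' Sample size for a one-way ANOVA omnibus test
#'
#' Smallest total N such that the noncentral-F tail probability beyond the
#' central-F critical value reaches the target power, with `df1 = k - 1`,
#' `df2 = N - k` and noncentrality `lambda = f^2 * N`.
#'
#' @param f Cohen's f effect size (> 0).
#' @param k Number of groups (>= 2).
#' @param alpha Type I error rate.
#' @param power Target power.
#' @param balanced If `TRUE`, N is constrained to multiples of `k` (equal
#'   group sizes, the G*Power convention); default `FALSE` returns the
#'   unconstrained minimum.
#' @param max_n Search ceiling (error if the power is unreachable below it).
#' @return Minimum total N (integer).
#' @export
anova_sample_size <- function(f, k, alpha = 0.05, power = 0.80,
                              balanced = FALSE, max_n = 1e6) {
  stopifnot(f > 0, k >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  achieved <- function(N) {
    crit <- stats::qf(1 - alpha, k - 1, N - k)
    1 - stats::pf(crit, k - 1, N - k, ncp = f^2 * N)
  }
  step <- if (balanced) k else 1L
  lo <- if (balanced) 2L * k else k + 1L
  if (achieved(lo) >= power) return(as.integer(lo))
  hi <- lo
  while (achieved(hi) < power) {
    hi <- hi * 2L
    if (hi > max_n) stopf("target power unreachable below N = %g", max_n)
  }
  # power is monotone in N here; bisect, then snap to the step grid
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (achieved(mid) >= power) hi <- mid else lo <- mid
  }
  n <- hi
  if (balanced && n %% k != 0) n <- n + (k - n %% k)
  as.integer(n)
}

#' Full nonparametric cluster comparison report
#'
#' Kruskal-Wallis + epsilon-squared per variable, Dunn-Bonferroni pairwise
#' matrices per variable, and the chi-square gender x cluster test.
#'
#' @param cohort Cohort data.frame (must contain `gender` for the chi-square
#'   block).
#' @param labels Cluster labels in cohort row order (or a `cluster_solution`).
#' @param input_vars,outcome_vars Variable sets to test; missing columns are
#'   skipped with a warning.
#' @param alpha Significance level for the pairwise flags.
#' @return `stats_report`: `input_tests` and `outcome_tests` data.frames
#'   (variable, H, df, p, epsilon_squared), `dunn` (named list of pairwise
#'   data.frames), `gender` (`chisq_result` or NULL).
#' @export
profile_report <- function(cohort, labels,
                           input_vars = input_variables()$variable,
                           outcome_vars = intersect(
                             outcome_variables()$variable, names(cohort)),
                           alpha = 0.05) {
  if (inherits(labels, "cluster_solution")) labels <- labels$participant_labels
  stopifnot(length(labels) == nrow(cohort))
  test_block <- function(vars) {
    vars_here <- intersect(vars, names(cohort))
    skipped <- setdiff(vars, vars_here)
    if (length(skipped)) {
      warning("skipping missing variable(s): ",
              paste(skipped, collapse = ", "))
    }
    rows <- lapply(vars_here, function(v) {
      kw <- kruskal_wallis(cohort[[v]], labels)
      data.frame(variable = v, H = kw$H, df = kw$df, p = kw$p,
                 epsilon_squared = kw$epsilon_squared,
                 stringsAsFactors = FALSE)
    })
    if (!length(rows)) return(NULL)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  input_tests <- test_block(input_vars)
  outcome_tests <- test_block(outcome_vars)
  dunn_vars <- intersect(c(input_vars, outcome_vars), names(cohort))
  dunn <- lapply(dunn_vars, function(v) {
    dunn_bonferroni(cohort[[v]], labels, alpha)
  })
  names(dunn) <- dunn_vars
  gender <- NULL
  if (!is.null(cohort$gender)) {
    gender <- chi_square_independence(table(labels, cohort$gender))
  }
  structure(list(input_tests = input_tests, outcome_tests = outcome_tests,
                 dunn = dunn, gender = gender, alpha = alpha),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report>\n")
  if (!is.null(x$input_tests)) {
    cat(sprintf("  input variables: %d Kruskal-Wallis tests (%d with p < %g)\n",
                nrow(x$input_tests), sum(x$input_tests$p < x$alpha), x$alpha))
  }
  if (!is.null(x$outcome_tests)) {
    cat(sprintf("  outcomes: %d tests (%d with p < %g)\n",
                nrow(x$outcome_tests), sum(x$outcome_tests$p < x$alpha),
                x$alpha))
  }
  if (!is.null(x$gender)) {
    cat(sprintf("  gender x cluster: X^2(%d) = %.2f, p = %.4g\n",
                x$gender$df, x$gender$statistic, x$gender$p))
  }
  invisible(x)
}
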