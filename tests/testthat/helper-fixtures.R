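# Shared fixtures and independent oracles used across test files.

# A tiny two-profile spec set on three variables with simple bounds.
tiny_specs <- function(sizes = c(10L, 10L), iqr = c(1, 1)) {
  vars <- c("daily_mvpa", "bmi_percentile", "school_enjoyment")
  list(
    profile_spec("A", sizes[1],
                 location = c(daily_mvpa = 60, bmi_percentile = 30,
                              school_enjoyment = 4),
                 spread = c(daily_mvpa = iqr[1] * 10,
                            bmi_percentile = iqr[1] * 10,
                            school_enjoyment = iqr[1] * 0.5),
                 girl_fraction = 0.4),
    profile_spec("B", sizes[2],
                 location = c(daily_mvpa = 20, bmi_percentile = 80,
                              school_enjoyment = 2.5),
                 spread = c(daily_mvpa = iqr[2] * 10,
                            bmi_percentile = iqr[2] * 10,
                            school_enjoyment = iqr[2] * 0.5),
                 girl_fraction = 0.6)
  )
}

# Build a 60-s count series directly from a counts vector (one day).
series_from_counts <- function(counts, day_type = "weekday", day = 1L,
                               pid = "P0001") {
  count_series(data.frame(participant_id = pid, day = day,
                          day_type = day_type,
                          epoch = seq_along(counts), counts = counts,
                          stringsAsFactors = FALSE), 60)
}

# Independent single Lloyd step: assign to nearest center, replace each
# center by the mean of its members (empty clusters keep the old center).
lloyd_step <- function(centers, x) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
  lab <- apply(d2, 1, which.min)
  out <- centers
  for (j in seq_len(nrow(centers))) {
    if (any(lab == j)) out[j, ] <- colMeans(x[lab == j, , drop = FALSE])
  }
  out
}

# Brute-force Davies-Bouldin from first principles (loops, no shared code).
db_bruteforce <- function(x, labels) {
  k <- max(labels)
  cent <- t(vapply(seq_len(k), function(j) {
    colMeans(x[labels == j, , drop = FALSE])
  }, numeric(ncol(x))))
  s <- vapply(seq_len(k), function(j) {
    rows <- which(labels == j)
    mean(vapply(rows, function(i) sqrt(sum((x[i, ] - cent[j, ])^2)), 0))
  }, 0)
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      m <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      worst <- max(worst, (s[i] + s[j]) / m)
    }
    total <- total + worst
  }
  total / k
}

# Exact Kruskal-Wallis permutation p (two or three groups, full enumeration).
kw_perm_p <- function(values, labels) {
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  n <- length(values)
  hstat <- function(lab) {
    unname(suppressWarnings(stats::kruskal.test(values, factor(lab)))$statistic)
  }
  h_obs <- hstat(labels)
  count <- 0L; total <- 0L
  if (length(sizes) == 2) {
    picks <- utils::combn(n, sizes[1])
    for (a in seq_len(ncol(picks))) {
      lab <- rep(2L, n); lab[picks[, a]] <- 1L
      total <- total + 1L
      if (hstat(lab) >= h_obs - 1e-9) count <- count + 1L
    }
  } else if (length(sizes) == 3) {
    picks1 <- utils::combn(n, sizes[1])
    for (a in seq_len(ncol(picks1))) {
      rest <- setdiff(seq_len(n), picks1[, a])
      picks2 <- utils::combn(length(rest), sizes[2])
      for (b in seq_len(ncol(picks2))) {
        lab <- rep(3L, n); lab[picks1[, a]] <- 1L; lab[rest[picks2[, b]]] <- 2L
        total <- total + 1L
        if (hstat(lab) >= h_obs - 1e-9) count <- count + 1L
      }
    }
  } else {
    stop("oracle supports 2 or 3 groups")
  }
  count / total
}

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# Chance-corrected agreement between two partitions (adjusted Rand index).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
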