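# Clustering of the SOM codebook: k-means++ / Lloyd, Davies-Bouldin index,
# cluster-count selection, participant label propagation.

# One k-means++ seeding + Lloyd run. Deterministic given the RNG state.
.kmeans_once <- function(x, k, max_iter = 100L) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowdist2(x, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k)[-1]) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowdist2(x, centers[j, , drop = FALSE])[, 1])
  }
  labels <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2m <- rowdist2(x, centers)
    new_labels <- max.col(-d2m, ties.method = "first")
    # empty clusters: re-seed from the point farthest from its centroid
    for (j in which(tabulate(new_labels, k) == 0)) {
      far <- which.max(d2m[cbind(seq_len(n), new_labels)])
      if (!length(far)) far <- 1L
      centers[j, ] <- x[far, ]
      d2m <- rowdist2(x, centers)
      new_labels <- max.col(-d2m, ties.method = "first")
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      if (any(labels == j)) {
        centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
      }
    }
  }
  wss <- sum(rowdist2(x, centers)[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, withinss = wss)
}

#' k-means on the codebook vectors
#'
#' Runs `restarts` k-means++ seeded Lloyd iterations and keeps the solution
#' with the lowest within-cluster sum of squares. Clusters that empty out
#' during iteration are re-seeded from the point farthest from its assigned
#' centroid. Deterministic under a fixed seed.
#'
#' @param codebook m x p matrix of neuron weight vectors (any point set
#'   works).
#' @param k Number of clusters, `2 <= k <= m`.
#' @param restarts Number of random restarts (default 100).
#' @param seed Integer seed.
#' @return List with `labels` (length m), `centers` (k x p) and `withinss`.
#' @export
kmeans_codebook <- function(codebook, k, restarts = 100L, seed = 1L) {
  codebook <- as.matrix(codebook)
  if (k > nrow(codebook)) {
    stopf("k = %d exceeds the number of points (%d)", k, nrow(codebook))
  }
  stopifnot(k >= 1, restarts >= 1)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      sol <- .kmeans_once(codebook, k)
      if (is.null(best) || sol$withinss < best$withinss - 1e-12) best <- sol
    }
    best
  })
}

#' Davies-Bouldin cluster-validity index
#'
#' `DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / M_ij`, where `S_i` is the
#' mean Euclidean distance of cluster i's members to its centroid and `M_ij`
#' the distance between centroids. Lower values indicate more distinct,
#' compact clusters.
#'
#' @param x Point matrix.
#' @param labels Integer cluster labels (1..k), every cluster non-empty.
#' @param centers Optional k x p centroid matrix; defaults to the cluster
#'   means of `x`.
#' @return Non-negative scalar.
#' @export
davies_bouldin <- function(x, labels, centers = NULL) {
  x <- as.matrix(x)
  k <- max(labels)
  if (k < 2) stopf("Davies-Bouldin needs at least 2 clusters")
  if (any(tabulate(labels, k) == 0)) stopf("empty cluster in labels")
  if (is.null(centers)) {
    centers <- do.call(rbind, lapply(seq_len(k), function(j) {
      colMeans(x[labels == j, , drop = FALSE])
    }))
  }
  # direct differences (not the expanded a^2 + b^2 - 2ab form) keep the
  # index accurate to ~1e-12 even when scatters are tiny relative to scale
  s <- vapply(seq_len(k), function(j) {
    dif <- sweep(x[labels == j, , drop = FALSE], 2, centers[j, ])
    mean(sqrt(rowSums(dif^2)))
  }, 0)
  m <- as.matrix(stats::dist(centers))
  ratios <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (m[i, j] == 0) {
        stopf("coincident centroids for clusters %d and %d", i, j)
      }
      ratios[i, j] <- (s[i] + s[j]) / m[i, j]
    }
  }
  mean(apply(ratios, 1, max, na.rm = TRUE))
}

#' Choose the cluster count by Davies-Bouldin minimization
#'
#' Runs [kmeans_codebook()] for every candidate k and picks the k with the
#' lowest Davies-Bouldin index; exact ties go to the smaller k (fewer
#' profiles).
#'
#' @param codebook Point matrix (typically the trained codebook).
#' @param k_range Candidate cluster counts (default 2:10).
#' @param restarts,seed Passed to [kmeans_codebook()] (each k uses a seed
#'   offset by its position, keeping the whole scan reproducible).
#' @return `cluster_solution` (without participant labels yet): `k`,
#'   `neuron_labels`, `centers`, `db_trace` (data.frame k, db, withinss).
#' @export
choose_k <- function(codebook, k_range = 2:10, restarts = 100L, seed = 1L) {
  codebook <- as.matrix(codebook)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(codebook)) {
    stopf("k_range exceeds the number of points (%d)", nrow(codebook))
  }
  sols <- vector("list", length(k_range))
  db <- rep(NA_real_, length(k_range))
  wss <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    sols[[i]] <- kmeans_codebook(codebook, k_range[i], restarts,
                                 seed = seed + i)
    db[i] <- tryCatch(
      davies_bouldin(codebook, sols[[i]]$labels, sols[[i]]$centers),
      error = function(e) NA_real_)
    wss[i] <- sols[[i]]$withinss
  }
  if (all(is.na(db))) stopf("Davies-Bouldin undefined for every candidate k")
  pick <- which.min(db)  # which.min takes the first (smallest k) on ties
  structure(
    list(k = k_range[pick], neuron_labels = sols[[pick]]$labels,
         centers = sols[[pick]]$centers,
         db_trace = data.frame(k = k_range, db = db, withinss = wss),
         participant_labels = NULL, hits = NULL),
    class = "cluster_solution"
  )
}

#' Propagate neuron cluster labels to participants
#'
#' Each participant inherits the cluster label of its best-matching unit on
#' the selected map; per-neuron hit counts (participants mapped to each
#' neuron) are recorded.
#'
#' @param som A `trained_som`.
#' @param solution A `cluster_solution` from [choose_k()].
#' @param x Native-scale data matrix (participants x variables, same columns
#'   the map was trained on).
#' @return The solution with `participant_labels` (named by row names of `x`
#'   when present) and `hits` (length m).
#' @export
assign_participants <- function(som, solution, x) {
  stopifnot(inherits(som, "trained_som"), inherits(solution, "cluster_solution"))
  z <- som_standardize(som, x)
  if (ncol(z) != ncol(som$codebook)) stopf("dimension mismatch with codebook")
  b <- bmu(som$codebook, z)
  best <- if (is.null(dim(b))) b[1] else b[, 1]
  solution$participant_labels <- stats::setNames(solution$neuron_labels[best],
                                                 rownames(x))
  solution$hits <- tabulate(best, nbins = nrow(som$codebook))
  solution
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d (Davies-Bouldin %.4f)\n", x$k,
              x$db_trace$db[x$db_trace$k == x$k]))
  if (!is.null(x$participant_labels)) {
    cat("  participants per cluster:",
        paste(tabulate(x$participant_labels, x$k), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-cluster medians and interquartile ranges
#'
#' Native-scale medians and IQRs per cluster for the requested variables,
#' using linear-interpolation quartiles (`stats::quantile` type 7).
#'
#' @param cohort Cohort data.frame.
#' @param solution A `cluster_solution` with participant labels (in cohort
#'   row order).
#' @param variables Columns to summarize; defaults to the input variables
#'   present in the cohort.
#' @return Data.frame: `variable`, then per cluster `median` and `iqr`
#'   columns plus a formatted `"median (IQR)"` string column.
#' @export
cluster_summary <- function(cohort, solution,
                            variables = intersect(input_variables()$variable,
                                                  names(cohort))) {
  labels <- solution$participant_labels
  stopifnot(!is.null(labels), length(labels) == nrow(cohort))
  k <- solution$k
  sizes <- tabulate(labels, k)
  if (any(sizes == 0)) {
    warning("empty cluster(s): ", paste(which(sizes == 0), collapse = ", "))
  }
  out <- data.frame(variable = variables, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    idx <- labels == j
    med <- vapply(variables, function(v) {
      if (!any(idx)) NA_real_ else stats::median(cohort[[v]][idx])
    }, 0)
    iqr <- vapply(variables, function(v) {
      if (!any(idx)) NA_real_ else stats::IQR(cohort[[v]][idx], type = 7)
    }, 0)
    out[[sprintf("cluster%d_median", j)]] <- med
    out[[sprintf("cluster%d_iqr", j)]] <- iqr
    out[[sprintf("cluster%d", j)]] <- ifelse(
      is.na(med), "-", sprintf("%.2f (%.2f)", med, iqr))
  }
  attr(out, "cluster_sizes") <- sizes
  out
}
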