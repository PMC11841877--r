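# Self-organizing map: initialization, neighborhood kernels, sequential and
# batch training, quantization and topographic errors.

.som_kinds <- c("gaussian", "bubble", "cutgauss", "ep")

#' Neighborhood kernel weight
#'
#' Weight given to a neuron at lattice distance `d` from the winner under
#' neighborhood radius `sigma`: gaussian `exp(-d^2 / (2 sigma^2))`; bubble
#' `1(d <= sigma)`; cutgauss, the gaussian value inside the bubble and 0
#' outside; ep (Epanechnikov) `max(0, 1 - (d/sigma)^2)`. A radius of 0
#' degrades every kernel to the winner-only indicator (used by the
#' k-means-equivalent limit of batch training).
#'
#' @param kind One of `"gaussian"`, `"bubble"`, `"cutgauss"`, `"ep"`.
#' @param d Lattice distance(s), >= 0.
#' @param sigma Neighborhood radius, >= 0.
#' @return Weight(s) in `[0, 1]`.
#' @export
neighborhood <- function(kind, d, sigma) {
  kind <- match.arg(kind, .som_kinds)
  stopifnot(all(d >= 0), sigma >= 0)
  if (sigma == 0) return(as.numeric(d == 0))
  switch(kind,
         gaussian = exp(-d^2 / (2 * sigma^2)),
         bubble   = as.numeric(d <= sigma),
         cutgauss = exp(-d^2 / (2 * sigma^2)) * (d <= sigma),
         ep       = pmax(0, 1 - (d / sigma)^2))
}

#' Random codebook initialization
#'
#' Each weight coordinate is drawn uniformly within the observed min-max of
#' the corresponding data column; a constant column yields that constant in
#' every neuron.
#'
#' @param grid A [som_grid()].
#' @param data Numeric matrix (cases x variables).
#' @param seed Integer seed.
#' @return m x p codebook matrix.
#' @export
init_random <- function(grid, data, seed = 1L) {
  stopifnot(inherits(grid, "som_grid"), nrow(data) >= 1)
  m <- n_units(grid)
  lo <- apply(data, 2, min)
  hi <- apply(data, 2, max)
  with_seed(seed, {
    w <- matrix(runif(m * ncol(data)), m, ncol(data))
    sweep(sweep(w, 2, hi - lo, "*"), 2, lo, "+")
  })
}

#' Linear codebook initialization
#'
#' Weights are laid out on the plane spanned by the two leading principal
#' components of the data: grid rows vary linearly along the first component
#' and grid columns along the second, each scaled by the component standard
#' deviation, centered on the data mean. Rank-1 data collapse the second axis
#' to zero with a warning.
#'
#' @inheritParams init_random
#' @return m x p codebook matrix.
#' @export
init_linear <- function(grid, data) {
  stopifnot(inherits(grid, "som_grid"), nrow(data) >= 2, ncol(data) >= 2)
  mu <- colMeans(data)
  eg <- eigen(stats::cov(data), symmetric = TRUE)
  sd1 <- sqrt(max(eg$values[1], 0))
  sd2 <- sqrt(max(eg$values[2], 0))
  if (sd2 <= sd1 * 1e-6) {
    warning("data are numerically rank-1; second initialization axis is zero")
    sd2 <- 0
  }
  row <- rep(seq_len(grid$height), each = grid$width)
  col <- rep(seq_len(grid$width), times = grid$height)
  u <- if (grid$height > 1) (2 * (row - 1) / (grid$height - 1) - 1) else rep(0, length(row))
  v <- if (grid$width > 1) (2 * (col - 1) / (grid$width - 1) - 1) else rep(0, length(col))
  w <- outer(u, sd1 * eg$vectors[, 1]) + outer(v, sd2 * eg$vectors[, 2])
  sweep(w, 2, mu, "+")
}

#' Best-matching units
#'
#' Winner and runner-up neuron per case by Euclidean distance to the codebook
#' vectors; ties are broken by the lowest neuron index.
#'
#' @param codebook m x p codebook matrix.
#' @param x A single input vector or an n x p matrix.
#' @return For a vector, `c(best, second)` (second is `NA` on a single-neuron
#'   map); for a matrix, an n x 2 integer matrix.
#' @export
bmu <- function(codebook, x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  if (anyNA(x) || any(!is.finite(x))) stopf("non-finite input to bmu()")
  if (ncol(x) != ncol(codebook)) stopf("dimension mismatch in bmu()")
  d2 <- rowdist2(x, codebook)
  best <- max.col(-d2, ties.method = "first")
  if (nrow(codebook) == 1) {
    out <- cbind(best, NA_integer_)
  } else {
    d2[cbind(seq_len(nrow(x)), best)] <- Inf
    second <- max.col(-d2, ties.method = "first")
    out <- cbind(best, second)
  }
  colnames(out) <- c("best", "second")
  if (single) out[1, ] else out
}

#' Default two-phase training schedule
#'
#' Rough phase: radius from `max(height, width) / 4` down to 1; fine-tuning:
#' 1 down to 0.5. Epoch counts follow the map-units-per-case convention
#' (`10 m / n` rough, `40 m / n` fine, floor 5). Sequential training adds a
#' linearly decaying learning rate per phase (0.5 -> 0.05 rough,
#' 0.05 -> 0.01 fine).
#'
#' @param grid A [som_grid()].
#' @param n Number of training cases.
#' @return List of two phase lists (`epochs`, `sigma0`, `sigmaf`, `eta0`,
#'   `etaf`).
#' @export
default_schedule <- function(grid, n) {
  m <- n_units(grid)
  list(
    rough = list(epochs = max(5L, as.integer(ceiling(10 * m / n))),
                 sigma0 = max(max(grid$height, grid$width) / 4, 1),
                 sigmaf = 1,
                 eta0 = 0.5, etaf = 0.05),
    fine  = list(epochs = max(5L, as.integer(ceiling(40 * m / n))),
                 sigma0 = 1, sigmaf = 0.5,
                 eta0 = 0.05, etaf = 0.01)
  )
}

.check_schedule <- function(phases) {
  for (ph in phases) {
    stopifnot(ph$epochs >= 1, ph$sigma0 >= ph$sigmaf, ph$sigmaf >= 0)
    if (!is.null(ph$eta0)) stopifnot(ph$eta0 >= 0, ph$eta0 <= 1)
  }
}

# Linear within-phase ramps, one value per step.
.phase_ramp <- function(from, to, steps) {
  if (steps == 1) return(from)
  from + (to - from) * (seq_len(steps) - 1) / (steps - 1)
}

#' Sequential (online) SOM training
#'
#' Cases are presented one at a time in a fresh random order per epoch; at
#' each step the winner is found by Euclidean distance and every neuron moves
#' toward the input by `eta(k) * h(d, sigma(k))`, with the learning rate and
#' radius decaying linearly within each phase.
#'
#' @param codebook Initial m x p codebook.
#' @param data n x p training matrix.
#' @param grid The [som_grid()] the codebook lives on.
#' @param kind Neighborhood kernel, see [neighborhood()].
#' @param schedule Phase list as produced by [default_schedule()].
#' @param seed Integer seed controlling the presentation order.
#' @return Trained m x p codebook.
#' @export
train_sequential <- function(codebook, data, grid, kind = "gaussian",
                             schedule = default_schedule(grid, nrow(data)),
                             seed = 1L) {
  if (!nrow(data)) stopf("empty training data")
  kind <- match.arg(kind, .som_kinds)
  .check_schedule(schedule)
  n <- nrow(data)
  with_seed(seed, {
    order_all <- integer(0)
    eta_all <- numeric(0)
    sigma_all <- numeric(0)
    for (ph in schedule) {
      steps <- ph$epochs * n
      ord <- unlist(lapply(seq_len(ph$epochs),
                           function(e) sample.int(n) - 1L))
      order_all <- c(order_all, ord)
      eta_all <- c(eta_all, .phase_ramp(ph$eta0, ph$etaf, steps))
      sigma_all <- c(sigma_all, .phase_ramp(ph$sigma0, ph$sigmaf, steps))
    }
    .cpp_train_seq(codebook, data, order_all, eta_all, sigma_all,
                   grid$dist, match(kind, .som_kinds) - 1L)
  })
}

#' Batch SOM training
#'
#' Per epoch, every case is assigned to its best-matching unit and every
#' neuron is replaced by the neighborhood-weighted mean of all cases,
#' `w_j = sum_i h(d(j, c(i))) x_i / sum_i h(d(j, c(i)))`; neurons receiving
#' zero total weight keep their previous vector. The radius decays linearly
#' over the concatenated epochs of the schedule. With radius 0 one epoch is
#' exactly one Lloyd k-means step on the codebook.
#'
#' @inheritParams train_sequential
#' @return Trained m x p codebook.
#' @export
train_batch <- function(codebook, data, grid, kind = "gaussian",
                        schedule = default_schedule(grid, nrow(data))) {
  if (!nrow(data)) stopf("empty training data")
  kind <- match.arg(kind, .som_kinds)
  .check_schedule(schedule)
  w <- codebook
  for (ph in schedule) {
    sig <- .phase_ramp(ph$sigma0, ph$sigmaf, ph$epochs)
    for (e in seq_len(ph$epochs)) {
      best <- max.col(-rowdist2(data, w), ties.method = "first")
      # h_mat[j, i] = h(d(j, bmu(i)), sigma): m x n
      h_mat <- matrix(neighborhood(kind, grid$dist[, best], sig[e]),
                      nrow = n_units(grid))
      den <- rowSums(h_mat)
      num <- h_mat %*% data
      upd <- den > 0
      w[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    }
  }
  w
}

#' Quantization error
#'
#' Mean Euclidean distance from each case to its best-matching unit.
#'
#' @param codebook m x p codebook.
#' @param data n x p matrix.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(codebook, data) {
  d2 <- rowdist2(data, codebook)
  mean(sqrt(apply(d2, 1, min)))
}

#' Topographic error
#'
#' Fraction of cases whose first and second best-matching units are not
#' adjacent on the lattice; 0 on a single-neuron map.
#'
#' @param codebook m x p codebook.
#' @param data n x p matrix.
#' @param grid The [som_grid()].
#' @return Proportion in `[0, 1]`.
#' @export
topographic_error <- function(codebook, data, grid) {
  if (nrow(codebook) == 1) return(0)
  b <- bmu(codebook, data)
  mean(!grid$adjacency[cbind(b[, 1], b[, 2])])
}

#' Train one self-organizing map
#'
#' Standardizes the inputs (z-score per variable by default), initializes the
#' codebook, trains with the requested mode and kernel, and reports the two
#' map-quality errors on the training data.
#'
#' @param x Numeric matrix (cases x variables) on the native scale.
#' @param grid A [som_grid()], or `NULL` to size the map from `n` and the
#'   leading-eigenvalue ratio via [map_size()].
#' @param mode `"sequential"` or `"batch"`.
#' @param kind Neighborhood kernel.
#' @param init `"random"` or `"linear"`.
#' @param seed Integer seed (random initialization and presentation order).
#' @param schedule Optional phase list; defaults to [default_schedule()].
#' @param standardize Z-score the columns before training (recommended: the
#'   input variables mix minutes, percentiles and Likert scores, and raw
#'   Euclidean distance would be dominated by the large-scale variables).
#' @return Object of class `trained_som`: `grid`, `codebook` (standardized
#'   space), `center`/`scale` (inverse transform), `mode`, `kind`, `init`,
#'   `schedule`, `seed`, `qe`, `te`.
#' @export
som_fit <- function(x, grid = NULL, mode = c("sequential", "batch"),
                    kind = "gaussian", init = c("random", "linear"),
                    seed = 1L, schedule = NULL, standardize = TRUE) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  kind <- match.arg(kind, .som_kinds)
  x <- as.matrix(x)
  if (!nrow(x)) stopf("empty training data")
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    center <- rep(0, ncol(x))
    scl <- rep(1, ncol(x))
  }
  z <- sweep(sweep(x, 2, center, "-"), 2, scl, "/")
  if (is.null(grid)) {
    hw <- map_size(nrow(z), eig_ratio(z))
    grid <- som_grid(hw[1], hw[2])
  }
  if (is.null(schedule)) schedule <- default_schedule(grid, nrow(z))
  cb <- if (init == "random") init_random(grid, z, seed) else init_linear(grid, z)
  cb <- if (mode == "sequential") {
    train_sequential(cb, z, grid, kind, schedule, seed)
  } else {
    train_batch(cb, z, grid, kind, schedule)
  }
  colnames(cb) <- colnames(x)
  structure(
    list(grid = grid, codebook = cb, center = center, scale = scl,
         mode = mode, kind = kind, init = init, schedule = schedule,
         seed = seed,
         qe = quantization_error(cb, z),
         te = topographic_error(cb, z, grid)),
    class = "trained_som"
  )
}

#' @export
print.trained_som <- function(x, ...) {
  cat(sprintf(
    "<trained_som> %d x %d hex map | %s training, %s kernel, %s init\n",
    x$grid$height, x$grid$width, x$mode, x$kind, x$init))
  cat(sprintf("  quantization error %.4f | topographic error %.4f\n",
              x$qe, x$te))
  invisible(x)
}

# Standardize new data with a trained map's parameters.
som_standardize <- function(som, x) {
  sweep(sweep(as.matrix(x), 2, som$center, "-"), 2, som$scale, "/")
}

#' Per-variable component planes on the native scale
#'
#' One `height x width` matrix per input variable, holding each neuron's
#' codebook value inverse-transformed to the variable's native scale.
#'
#' @param som A `trained_som`.
#' @return Named list of matrices (rows = lattice rows).
#' @export
export_component_planes <- function(som) {
  stopifnot(inherits(som, "trained_som"))
  native <- sweep(sweep(som$codebook, 2, som$scale, "*"), 2, som$center, "+")
  planes <- lapply(seq_len(ncol(native)), function(j) {
    matrix(native[, j], nrow = som$grid$height, ncol = som$grid$width,
           byrow = TRUE)
  })
  names(planes) <- colnames(native)
  planes
}
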