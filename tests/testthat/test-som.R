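# Hexagonal grid, initialization, winner search, training, map errors.

test_that("map sizing reproduces the reference layout and small cases", {
  expect_equal(unname(map_size(194, 4)), c(12, 6))
  expect_equal(unname(map_size(4, 1)), c(4, 3))   # covers ceil(5*sqrt(4)) = 10
  # symmetric data always give the squarest feasible grid
  for (n in c(10, 50, 100)) {
    hw <- map_size(n, 1)
    m <- ceiling(5 * sqrt(n))
    expect_gte(hw[1] * hw[2], m)
    expect_equal(unname(hw[2]), max(1, round(sqrt(m))))
  }
  # degenerate covariance: ratio capped, not an error
  expect_silent(map_size(50, Inf))
})

test_that("hexagonal sheet adjacency matches the lattice pair count", {
  # horizontal pairs h(w-1); between adjacent rows 2w-1 pairs
  for (h in 1:6) {
    for (w in 1:6) {
      g <- som_grid(h, w)
      expected <- h * (w - 1) + (h - 1) * (2 * w - 1)
      expect_equal(sum(g$adjacency) / 2, expected,
                   label = sprintf("%dx%d", h, w))
      expect_true(isSymmetric(g$adjacency))
    }
  }
  # interior neurons of a large-enough sheet have exactly six neighbors
  g <- som_grid(5, 5)
  idx <- as.vector(outer(2:4, 2:4, function(r, c) (r - 1) * 5 + c))
  expect_true(all(rowSums(g$adjacency)[idx] == 6))
})

test_that("neighborhood kernels match their closed forms", {
  expect_equal(neighborhood("gaussian", 0, 2), 1)
  expect_equal(neighborhood("gaussian", 2, 2), exp(-1 / 2))
  expect_equal(neighborhood("bubble", 2, 2), 1)
  expect_equal(neighborhood("bubble", 2 + 1e-9, 2), 0)
  expect_equal(neighborhood("cutgauss", 1, 2), exp(-1 / 8))
  expect_equal(neighborhood("cutgauss", 2.5, 2), 0)
  expect_equal(neighborhood("ep", 1, 2), 0.75)
  expect_equal(neighborhood("ep", 3, 2), 0)
  expect_error(neighborhood("triangle", 1, 1), "arg")
})

test_that("random initialization stays in per-column ranges, is seeded", {
  g <- som_grid(4, 4)
  x <- cbind(a = runif(30, -2, 5), b = rep(7, 30), c = rnorm(30))
  cb1 <- init_random(g, x, seed = 3)
  cb2 <- init_random(g, x, seed = 3)
  expect_identical(cb1, cb2)
  expect_true(all(cb1[, 1] >= min(x[, 1]) & cb1[, 1] <= max(x[, 1])))
  expect_equal(cb1[, 2], rep(7, 16))
})

test_that("linear initialization spans the leading principal plane", {
  set.seed(8)
  g <- som_grid(6, 4)
  # data on an exact 2-D plane in 4-D space
  basis <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  scores <- cbind(rnorm(100, sd = 3), rnorm(100, sd = 1))
  mu <- c(1, -2, 0.5, 4)
  x <- sweep(scores %*% t(basis), 2, mu, "+")
  cb <- init_linear(g, x)
  expect_equal(colMeans(cb), colMeans(x), tolerance = 1e-8)
  # all codebook vectors lie on the data plane
  resid <- sweep(cb, 2, colMeans(x), "-") %*%
    (diag(4) - basis %*% t(basis))
  expect_lt(max(abs(resid)), 1e-8)
  # corner-to-corner difference along height is proportional to the first
  # principal axis (independent eigendecomposition oracle)
  pc1 <- eigen(cov(x), symmetric = TRUE)$vectors[, 1]
  delta <- cb[1, ] - cb[nrow(cb) - g$width + 1, ]
  cosang <- sum(delta * pc1) / sqrt(sum(delta^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-8)
  # rank-1 data: second axis dropped with a warning
  x1 <- outer(rnorm(50), c(1, 2, 0, -1))
  expect_warning(init_linear(g, x1), "rank-1")
})

test_that("winner search minimizes distance with lowest-index ties", {
  cb <- rbind(c(0, 0), c(1, 1))
  expect_equal(unname(bmu(cb, c(0.1, 0))["best"]), 1)
  expect_equal(unname(bmu(cb, c(1, 1))["best"]), 2)
  expect_equal(unname(bmu(cb, c(0.5, 0.5))["best"]), 1)  # tie -> lowest index
  b <- bmu(cb, rbind(c(0, 0.2), c(2, 2)))
  expect_equal(unname(b[, "best"]), c(1, 2))
  expect_equal(unname(b[, "second"]), c(2, 1))
  expect_error(bmu(cb, c(NA, 1)), "finite")
  expect_error(bmu(cb, c(1, 2, 3)), "dimension")
})

test_that("sequential updates follow the learning rule", {
  g1 <- som_grid(1, 1)
  sched <- list(list(epochs = 1, sigma0 = 1, sigmaf = 1, eta0 = 0.5,
                     etaf = 0.5))
  w <- train_sequential(matrix(0, 1, 1), matrix(1, 1, 1), g1,
                        kind = "gaussian", schedule = sched, seed = 1)
  expect_equal(w[1, 1], 0.5)
  # zero learning rate leaves the codebook untouched
  sched0 <- list(list(epochs = 3, sigma0 = 1, sigmaf = 1, eta0 = 0,
                      etaf = 0))
  g <- som_grid(2, 2)
  cb <- matrix(rnorm(8), 4, 2)
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(train_sequential(cb, x, g, schedule = sched0, seed = 2), cb)
  # reproducibility under the seed
  sched2 <- default_schedule(g, 10)
  expect_identical(train_sequential(cb, x, g, schedule = sched2, seed = 7),
                   train_sequential(cb, x, g, schedule = sched2, seed = 7))
  expect_error(train_sequential(cb, x[0, , drop = FALSE], g), "empty")
})

test_that("a single-neuron sequential map converges to the data mean", {
  g1 <- som_grid(1, 1)
  sched <- list(list(epochs = 200, sigma0 = 1, sigmaf = 1, eta0 = 0.5,
                     etaf = 0.001))
  for (seed in c(1, 2, 3)) {
    x <- with_seed_test(seed, matrix(rnorm(60, mean = 2), 30, 2))
    w <- train_sequential(matrix(0, 1, 2), x, g1, schedule = sched,
                          seed = seed)
    expect_lt(max(abs(w - colMeans(x))), 0.05)
  }
})

test_that("batch training gives the neighborhood-weighted mean fixed points", {
  g1 <- som_grid(1, 1)
  x <- matrix(c(1, 3, 5, 7), 4, 1)
  sched <- list(list(epochs = 1, sigma0 = 1, sigmaf = 1))
  expect_equal(train_batch(matrix(0, 1, 1), x, g1, schedule = sched)[1, 1], 4)
  # codebook equal to data with distinct BMUs and zero radius: fixed point
  g <- som_grid(2, 2)
  cb <- rbind(c(0, 0), c(5, 0), c(0, 5), c(5, 5))
  sched0 <- list(list(epochs = 3, sigma0 = 0, sigmaf = 0))
  expect_equal(train_batch(cb, cb, g, kind = "bubble", schedule = sched0), cb)
})

test_that("zero-radius batch epochs are exact Lloyd steps", {
  set.seed(42)
  for (r in 1:20) {
    n <- sample(6:15, 1); p <- sample(2:4, 1); m <- 4
    x <- matrix(rnorm(n * p), n, p)
    cb <- matrix(rnorm(m * p), m, p)
    g <- som_grid(2, 2)
    sched <- list(list(epochs = 1, sigma0 = 0, sigmaf = 0))
    got <- train_batch(cb, x, g, kind = "bubble", schedule = sched)
    expect_equal(got, lloyd_step(cb, x), tolerance = 1e-10)
  }
})

test_that("zero-radius batch training never increases the k-means objective", {
  set.seed(5)
  x <- matrix(rnorm(200), 100, 2)
  cb <- matrix(rnorm(12), 6, 2)
  g <- som_grid(3, 2)
  msd <- function(w) {
    d2 <- outer(rowSums(x^2), rep(1, nrow(w))) +
      outer(rep(1, nrow(x)), rowSums(w^2)) - 2 * x %*% t(w)
    mean(apply(d2, 1, min))
  }
  obj <- msd(cb)
  for (e in 1:8) {
    cb <- train_batch(cb, x, g, kind = "bubble",
                      schedule = list(list(epochs = 1, sigma0 = 0,
                                           sigmaf = 0)))
    obj_new <- msd(cb)
    expect_lte(obj_new, obj + 1e-12)
    obj <- obj_new
  }
})

test_that("batch codebooks stay inside per-coordinate data ranges", {
  set.seed(11)
  x <- matrix(runif(300, -3, 9), 100, 3)
  g <- som_grid(4, 3)
  cb <- init_random(g, x, seed = 2)
  w <- train_batch(cb, x, g, kind = "gaussian",
                   schedule = default_schedule(g, 100))
  for (j in 1:3) {
    expect_true(all(w[, j] >= min(x[, j]) - 1e-12 &
                      w[, j] <= max(x[, j]) + 1e-12))
  }
})

test_that("quantization error is the mean BMU distance", {
  cb <- rbind(c(0, 0), c(10, 0))
  x <- rbind(c(0, 2), c(10, 0))
  expect_equal(quantization_error(cb, x), 1)  # (2 + 0) / 2
  expect_equal(quantization_error(cb, cb), 0)
  expect_equal(quantization_error(cb, x[2:1, ]), 1)  # order invariance
})

test_that("topographic error counts non-adjacent BMU pairs", {
  g <- som_grid(2, 2)
  # neurons 1 and 4 are the only non-adjacent pair on a 2x2 hex sheet
  expect_false(g$adjacency[1, 4])
  expect_true(all(g$adjacency[cbind(c(1, 1, 2, 2, 3), c(2, 3, 3, 4, 4))]))
  cb <- rbind(c(0, 0), c(10, 0), c(0, 10), c(0.5, 0))
  # points and their two nearest codebook vectors (manual count):
  x <- rbind(c(0.1, 0),   # 1st: neuron 1, 2nd: neuron 4 -> NOT adjacent
             c(0.45, 0),  # 1st: 4, 2nd: 1 -> NOT adjacent
             c(9, 0),     # 1st: 2, 2nd: 4 -> adjacent
             c(0, 9))     # 1st: 3, 2nd: 1 -> adjacent
  expect_equal(topographic_error(cb, x, g), 0.5)
  expect_equal(topographic_error(cb, rbind(c(9, 0), c(0, 9)), g), 0)
  expect_equal(topographic_error(cb, rbind(c(0.1, 0)), g), 1)
  expect_equal(topographic_error(matrix(0, 1, 2), x[, 1:2], g), 0)
})

test_that("component planes return native-scale matrices per variable", {
  coh <- generate_cohort(tiny_specs(), seed = 6)
  x <- cohort_matrix(coh, c("daily_mvpa", "bmi_percentile",
                            "school_enjoyment"))
  s <- som_fit(x, grid = som_grid(3, 3), mode = "batch", init = "linear",
               seed = 1)
  planes <- export_component_planes(s)
  expect_named(planes, colnames(x))
  expect_equal(dim(planes[[1]]), c(3, 3))
  # native scale: batch weighted means stay within the data range
  for (v in names(planes)) {
    expect_true(all(planes[[v]] >= min(x[, v]) - 1e-9 &
                      planes[[v]] <= max(x[, v]) + 1e-9))
  }
})
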