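# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Squared Euclidean distances between rows of `x` (n x p) and rows of
# `y` (m x p); returns n x m matrix. Clamps tiny negatives from rounding.
rowdist2 <- function(x, y) {
  d2 <- matrix(rowSums(x^2), nrow(x), nrow(y)) +
    matrix(rowSums(y^2), nrow(x), nrow(y), byrow = TRUE) -
    2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

# md5 of an arbitrary R object (via serialization to a temp file); used for
# pipeline manifests.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
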