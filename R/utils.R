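#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans hclust cutree dist rnorm runif rbinom rnbinom
#'   rlnorm plogis as.dist
#' @importFrom utils read.csv write.csv read.delim read.table count.fields
NULL

# Deterministic per-task seed derivation from a master seed. Stays below
# 2^31 so the result is always a valid R integer.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (v in idx) {
    s <- (s * 48271 + as.double(v) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs
# user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Squared Euclidean cross-distances between the rows of two matrices.
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
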