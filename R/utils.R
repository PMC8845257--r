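# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Draw one sub-seed per replicate from a master seed, keeping values in the
# 32-bit signed range so they are themselves valid seeds.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

# Symmetric inverse square root of a covariance matrix. Near-singular input
# (smallest eigenvalue < 1e-10) gets a ridge of 1e-8 with a warning, which
# keeps deep-polytomy phylogenetic covariances usable.
mat_inv_sqrt <- function(C, ridge = 1e-8, tol = 1e-10) {
  eig <- eigen(C, symmetric = TRUE)
  if (min(eig$values) < tol) {
    warning("covariance matrix near-singular; adding ridge ", ridge)
    C <- C + diag(ridge, nrow(C))
    eig <- eigen(C, symmetric = TRUE)
  }
  eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
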