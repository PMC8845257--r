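# Shared fixtures and independent oracles. Oracles deliberately take a
# different computational route than the package functions they check.

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

write_tmp_newick <- function(txt) {
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  f
}

# random bifurcating/polytomous tree with Grafen depth-1 branch lengths
random_grafen_tree <- function(n) {
  grafen_branch_lengths(ape::rtree(n, br = NULL))
}

# Brownian motion via the covariance matrix (independent of the package's
# pre-order branch-increment simulator)
bm_via_chol <- function(C, q = 1) {
  L <- chol(C)
  out <- t(L) %*% matrix(stats::rnorm(nrow(C) * q), nrow(C), q)
  rownames(out) <- rownames(C)
  out
}

# classical univariate Blomberg K through explicit quadratic forms
oracle_blomberg_k <- function(y, C) {
  n <- length(y)
  Ci <- solve(C)
  one <- rep(1, n)
  ahat <- as.numeric((t(one) %*% Ci %*% y) / (t(one) %*% Ci %*% one))
  mse0 <- as.numeric(t(y - ahat) %*% (y - ahat)) / (n - 1)
  mse <- as.numeric(t(y - ahat) %*% Ci %*% (y - ahat)) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  (mse0 / mse) / expected
}

# ordinary (non-phylogenetic) two-block PLS first-pair correlation
oracle_ordinary_pls_r <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc) / (nrow(X) - 1))
  stats::cor(drop(Xc %*% s$u[, 1]), drop(Yc %*% s$v[, 1]))
}

# 5-tip ultrametric fixture used by the phylogenetic-signal oracle test
k_fixture_tree <- function() {
  ape::read.tree(text = "(((A:0.3,B:0.3):0.4,C:0.7):0.3,(D:0.5,E:0.5):0.5);")
}
k_fixture_y <- c(A = 1.2, B = 0.9, C = 0.3, D = -0.8, E = -1.1)
k_fixture_value <- 1.853183399243  # frozen from oracle_blomberg_k

# small synthetic dataset on disk for pipeline tests
write_pipeline_fixture <- function(dir, n = 24, seed = 7, k_true = 4) {
  scn <- synthetic_scenario(n_species = n, k_true = k_true,
                            n_traits = 12, shifted_traits = 1:6)
  write_synthetic_dataset(scn, dir, seed = seed)
}
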