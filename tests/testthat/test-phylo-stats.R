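test_that("phylo_gls_mean reduces to arithmetic means and handles constants", {
  set.seed(31)
  Y <- matrix(stats::rnorm(20), 10, 2)
  expect_equal(drop(phylo_gls_mean(Y, diag(10))), colMeans(Y))
  const <- matrix(3.5, 6, 1)
  tr <- random_grafen_tree(6)
  expect_equal(drop(phylo_gls_mean(const, phylo_vcv(tr))), 3.5)
  expect_equal(drop(phylo_gls_mean(matrix(c(0, 2), 2, 1), diag(2))), 1)
})

test_that("phylo_transform whitens the phylogenetic covariance", {
  set.seed(32)
  for (i in 1:20) {
    tr <- random_grafen_tree(sample(5:15, 1))
    C <- phylo_vcv(tr)
    P <- ecomorphr:::mat_inv_sqrt(C)
    expect_lt(max(abs(P %*% C %*% t(P) - diag(nrow(C)))), 1e-8)
  }
  # identity C: plain column centering
  Y <- matrix(stats::rnorm(24), 8, 3)
  expect_equal(phylo_transform(Y, diag(8)), scale(Y, scale = FALSE),
               ignore_attr = TRUE)
})

test_that("phylo_pls is exact for duplicated blocks and matches the ordinary
           PLS oracle on a star tree", {
  set.seed(33)
  tr <- random_grafen_tree(12)
  C <- phylo_vcv(tr)
  X <- bm_via_chol(C, 3)
  fit_same <- phylo_pls(X, X, C, n_perm = 49, seed = 1)
  expect_equal(fit_same$r, 1, tolerance = 1e-10)
  # star phylogeny: C = I, must equal ordinary two-block PLS
  n <- 10
  Xs <- matrix(stats::rnorm(n * 3), n, 3)
  Ys <- matrix(stats::rnorm(n * 4), n, 4)
  fit <- phylo_pls(Xs, Ys, diag(n), n_perm = 49, seed = 1)
  expect_equal(fit$r, oracle_ordinary_pls_r(Xs, Ys), tolerance = 1e-8)
  expect_equal(sum(fit$x_loadings^2), 1, tolerance = 1e-10)
  expect_equal(sum(fit$y_loadings^2), 1, tolerance = 1e-10)
})

test_that("phylo_pls r is invariant to orthogonal rotation of either block", {
  set.seed(34)
  tr <- random_grafen_tree(14)
  C <- phylo_vcv(tr)
  X <- bm_via_chol(C, 3)
  Y <- bm_via_chol(C, 4)
  r0 <- phylo_pls(X, Y, C, n_perm = 9, seed = 1)$r
  Qx <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  Qy <- qr.Q(qr(matrix(stats::rnorm(16), 4, 4)))
  expect_equal(phylo_pls(X %*% Qx, Y, C, n_perm = 9, seed = 1)$r, r0,
               tolerance = 1e-10)
  expect_equal(phylo_pls(X, Y %*% Qy, C, n_perm = 9, seed = 1)$r, r0,
               tolerance = 1e-10)
})

test_that("permutation statistics are reproducible and honor +1 convention", {
  set.seed(35)
  tr <- random_grafen_tree(12)
  C <- phylo_vcv(tr)
  X <- bm_via_chol(C, 2); Y <- bm_via_chol(C, 3)
  f1 <- phylo_pls(X, Y, C, n_perm = 199, seed = 42)
  f2 <- phylo_pls(X, Y, C, n_perm = 199, seed = 42)
  expect_identical(f1$p, f2$p)
  expect_identical(f1$z, f2$z)
  expect_gte(f1$p, 1 / 200)
  g <- rep(1:3, each = 4)
  m1 <- rrpp_manova(Y, g, C, n_perm = 199, seed = 42)
  m2 <- rrpp_manova(Y, g, C, n_perm = 199, seed = 42)
  expect_identical(m1$table$p[1], m2$table$p[1])
  expect_gte(m1$table$p[1], 1 / 200)
  k1 <- physignal(Y, C, n_perm = 199, seed = 42)
  expect_identical(k1$p, physignal(Y, C, n_perm = 199, seed = 42)$p)
})

test_that("physignal matches the univariate Blomberg K oracle and errors on
           star trees", {
  tr <- k_fixture_tree()
  C <- ape::vcv.phylo(tr)
  y <- k_fixture_y[rownames(C)]
  fit <- physignal(y, C, n_perm = 99, seed = 1)
  expect_equal(fit$K, k_fixture_value, tolerance = 1e-9)
  expect_equal(fit$K, oracle_blomberg_k(y, C), tolerance = 1e-12)
  expect_equal(fit$scope, "univariate")
  set.seed(36)
  Ym <- bm_via_chol(C, 3)
  expect_equal(physignal(Ym, C, n_perm = 9, seed = 1)$scope, "multivariate")
  expect_error(physignal(y, diag(5), n_perm = 9), "star")
})

test_that("BM-simulated traits give K near 1 and shuffled traits lose signal", {
  set.seed(37)
  tr <- simulate_tree(40, seed = 5)
  C <- phylo_vcv(tr)
  ks <- replicate(60, {
    y <- bm_via_chol(C)
    physignal(y, C, n_perm = 9, seed = 1)$K
  })
  expect_gt(mean(ks), 0.8)
  expect_lt(mean(ks), 1.2)
  # iid traits: K well below the BM calibration on average
  ks0 <- replicate(60, physignal(stats::rnorm(40), C, n_perm = 9,
                                 seed = 1)$K)
  expect_lt(mean(ks0), mean(ks))
})

test_that("rrpp_manova equals classical one-way ANOVA for C = I, q = 1", {
  set.seed(38)
  y <- stats::rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  fit <- rrpp_manova(matrix(y), g, diag(18), n_perm = 99, seed = 1)
  ref <- stats::anova(stats::lm(y ~ g))
  expect_equal(fit$table$F[1], ref$`F value`[1], tolerance = 1e-10)
  expect_equal(fit$table$Df[1:2], ref$Df)
  expect_equal(fit$table$SS[1:2], ref$`Sum Sq`, tolerance = 1e-10)
})

test_that("rrpp_manova table satisfies its structural invariants", {
  set.seed(39)
  tr <- random_grafen_tree(20)
  C <- phylo_vcv(tr)
  Y <- bm_via_chol(C, 5)
  g <- rep(1:4, each = 5)
  fit <- rrpp_manova(Y, g, C, n_perm = 99, seed = 3)
  tab <- fit$table
  expect_equal(tab$SS[1] + tab$SS[2], tab$SS[3], tolerance = 1e-8)
  expect_equal(tab$Df[1] + tab$Df[2], tab$Df[3])
  expect_equal(tab$Rsq[1], tab$SS[1] / tab$SS[3], tolerance = 1e-12)
  expect_error(rrpp_manova(Y, rep(1, 20), C), "two groups")
  expect_error(rrpp_manova(Y, c(rep(1, 19), 2), C), "two members")
})

test_that("strong group separation is detected with high power", {
  set.seed(40)
  pvals <- replicate(20, {
    tr <- simulate_tree(30, seed = sample.int(1e6, 1))
    C <- phylo_vcv(tr)
    Y <- bm_via_chol(C, 6)
    g <- sample(rep(1:3, each = 10))
    Y[g == 2, 1:3] <- Y[g == 2, 1:3] + 2
    Y[g == 3, 4:6] <- Y[g == 3, 4:6] - 2
    rrpp_manova(Y, g, C, n_perm = 199, seed = 1)$table$p[1]
  })
  expect_gte(mean(pvals < 0.05), 0.9)
})

test_that("pairwise_group_tests flags only shifted pairs and matches the
           global test for k = 2", {
  set.seed(41)
  tr <- simulate_tree(36, seed = 9)
  C <- phylo_vcv(tr)
  Y <- bm_via_chol(C, 4)
  g <- sample(rep(1:3, each = 12))
  Y[g == 3, ] <- Y[g == 3, ] + 3      # only group 3 is displaced
  fit <- rrpp_manova(Y, g, C, n_perm = 499, seed = 2)
  pw <- pairwise_group_tests(fit)
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$d >= 0))
  with3 <- pw$group1 == "3" | pw$group2 == "3"
  expect_true(all(pw$p[with3] < 0.05))
  expect_gt(pw$p[!with3], 0.05)
  # k = 2: the single pairwise contrast agrees with the global test
  g2 <- sample(rep(1:2, each = 18))
  Y2 <- bm_via_chol(C, 3)
  fit2 <- rrpp_manova(Y2, g2, C, n_perm = 999, seed = 4)
  pw2 <- pairwise_group_tests(fit2)
  expect_equal(nrow(pw2), 1L)
  expect_lt(abs(pw2$p - fit2$table$p[1]), 0.12)
})

test_that("group_means_pca preserves inter-mean geometry", {
  set.seed(42)
  Y <- matrix(stats::rnorm(60), 20, 3)
  g <- rep(1:4, each = 5)
  gm <- group_means_pca(Y, g)
  B <- ecomorphr:::gls_group_means(rrpp_manova(Y, g, diag(20), n_perm = 9,
                                               seed = 1))
  expect_equal(as.matrix(stats::dist(gm$means)), as.matrix(stats::dist(B)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # k = 2 in 2D: means live on PC1 only
  g2 <- rep(1:2, each = 10)
  gm2 <- group_means_pca(Y[, 1:2], g2)
  expect_equal(ncol(gm2$means), 1L)
  expect_length(gm2$group_cov, 2L)
})
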