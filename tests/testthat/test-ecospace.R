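test_that("jaccard_distance counts shared against union presences", {
  M <- microhabitat_matrix(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 1, 0, 0),
                                 c(0, 0, 0, 1)),
                           species_ids = c("a", "b", "c", "d"),
                           descriptor_names = paste0("d", 1:4))
  D <- jaccard_distance(M)
  expect_equal(unname(D["a", "b"]), 2 / 3)   # 1 shared of 3 in union
  expect_equal(unname(D["a", "c"]), 0)       # identical profiles
  expect_equal(unname(D["a", "d"]), 1)       # disjoint profiles
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_true(isSymmetric(unclass(D)))
})

test_that("jaccard_distance is a metric on random binary matrices", {
  set.seed(21)
  worst <- 0
  for (i in seq_len(1000)) {
    n <- sample(3:8, 1); m <- sample(2:6, 1)
    vals <- matrix(stats::rbinom(n * m, 1, 0.5), n, m)
    vals[rowSums(vals) == 0, 1] <- 1L
    D <- unclass(jaccard_distance(
      microhabitat_matrix(vals, species_ids = sprintf("s%d", 1:n),
                          descriptor_names = sprintf("d%d", 1:m))))
    for (c in 1:n)  # violation of d(a,b) <= d(a,c) + d(c,b)
      worst <- max(worst, max(D - outer(D[, c], D[c, ], "+")))
  }
  expect_lte(worst, 1e-12)
})

test_that("pcoa embeds Euclidean distances exactly and respects symmetry", {
  # three equidistant points: two retained axes with equal eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  o3 <- pcoa(D3)
  expect_equal(ncol(o3$scores), 2L)
  expect_equal(o3$eigenvalues[1], o3$eigenvalues[2], tolerance = 1e-10)
  # collinear points: one axis, distances reproduced exactly
  x <- c(0, 1, 3, 7)
  D <- as.matrix(stats::dist(x))
  o <- pcoa(D)
  expect_equal(ncol(o$scores), 1L)
  expect_equal(as.matrix(stats::dist(o$scores)), D, tolerance = 1e-10,
               ignore_attr = TRUE)
  # general Euclidean input reconstructs to 1e-8
  set.seed(5)
  P <- matrix(stats::rnorm(30), 10, 3)
  DP <- as.matrix(stats::dist(P))
  oP <- pcoa(DP)
  expect_lt(max(abs(as.matrix(stats::dist(oP$scores)) - DP)), 1e-8)
  # eigenvalues ordered decreasing, scores orthogonal
  dat <- simulate_dataset(synthetic_scenario(n_species = 20), seed = 2)
  oJ <- pcoa(jaccard_distance(dat$habitat))
  expect_true(all(diff(oJ$eigenvalues) <= 1e-10))
  G <- crossprod(oJ$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("pcoa agrees with the ape reference implementation", {
  dat <- simulate_dataset(synthetic_scenario(n_species = 15), seed = 3)
  D <- jaccard_distance(dat$habitat)
  mine <- pcoa(D)
  ref <- ape::pcoa(stats::as.dist(unclass(D)))
  pos <- ref$values$Eigenvalues > 1e-8 * max(ref$values$Eigenvalues)
  expect_equal(mine$eigenvalues, ref$values$Eigenvalues[pos],
               tolerance = 1e-8)
  expect_equal(abs(mine$scores[, 1]),
               abs(ref$vectors[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("select_k_plateau implements the first-gain-below-epsilon rule", {
  # range 53, threshold 2.65; first sub-threshold gain is k=2 -> 3
  expect_equal(select_k_plateau(c(-100, -50, -48, -47), eps = 0.05), 2L)
  # steeply increasing curve: no plateau, argmax fallback
  expect_equal(select_k_plateau(c(0, 100, 250, 450), eps = 0.05), 4L)
  # flat curve: k = 1
  expect_equal(select_k_plateau(rep(5, 4), eps = 0.05), 1L)
  expect_error(select_k_plateau(c(1, 2)), "three")
  expect_error(select_k_plateau(c(1, 2, 3), eps = 0), "eps")
})

test_that("kmeans_cluster recovers separated blobs and honors edge cases", {
  set.seed(6)
  X <- rbind(matrix(stats::rnorm(40, 0), 20, 2),
             matrix(stats::rnorm(40, 8), 20, 2))
  rownames(X) <- sprintf("s%02d", 1:40)
  truth <- rep(1:2, each = 20)
  cm <- kmeans_cluster(X, 2, restarts = 10, seed = 1)
  expect_equal(adjusted_rand_index(cm$assignments, truth), 1)
  # deterministic given seed
  cm2 <- kmeans_cluster(X, 2, restarts = 10, seed = 1)
  expect_identical(cm$assignments, cm2$assignments)
  # k = 1: center is the column means
  c1 <- kmeans_cluster(X, 1, restarts = 2, seed = 1)
  expect_equal(unname(c1$centers), matrix(colMeans(X), 1), tolerance = 1e-8)
  # k = n: zero inertia
  cn <- kmeans_cluster(X[1:6, ], 6, restarts = 5, seed = 1)
  expect_equal(cn$inertia, 0, tolerance = 1e-16)
  expect_error(kmeans_cluster(X, 0), "k must lie")
})

test_that("descriptor-axis and cluster affiliation correlations behave", {
  dat <- simulate_dataset(synthetic_scenario(n_species = 30), seed = 4)
  ord <- pcoa(jaccard_distance(dat$habitat))
  TA <- suppressWarnings(trait_axis_correlation(dat$habitat, ord))
  expect_equal(dim(TA), c(ncol(dat$habitat), ncol(ord$scores)))
  expect_true(all(abs(TA) <= 1 + 1e-12))
  # a descriptor equal to an axis sign pattern correlates at |1|
  M2 <- unclass(dat$habitat)
  M2[, 1] <- as.integer(ord$scores[, 1] > stats::median(ord$scores[, 1]))
  if (any(rowSums(M2) == 0)) M2[rowSums(M2) == 0, 2] <- 1L
  TA2 <- suppressWarnings(trait_axis_correlation(
    microhabitat_matrix(M2, species_ids = rownames(M2),
                        descriptor_names = colnames(M2)), ord))
  expect_gt(abs(TA2[1, 1]), 0.8)
  # constant column -> zero with warning
  M3 <- unclass(dat$habitat)
  M3[, 2] <- 1L
  expect_warning(
    TA3 <- trait_axis_correlation(
      microhabitat_matrix(M3, species_ids = rownames(M3),
                          descriptor_names = colnames(M3)), ord),
    "constant")
  expect_equal(unname(TA3[2, ]), rep(0, ncol(ord$scores)))

  cm <- kmeans_cluster(ord$scores, 4, restarts = 20, seed = 1)
  A <- suppressWarnings(cluster_trait_affiliation(TA, cm))
  expect_equal(dim(A), c(nrow(TA), 4L))
  expect_true(all(abs(A) <= 1 + 1e-12))
  # center collinear with a descriptor profile -> affiliation ~ 1
  cm2 <- cm
  cm2$centers[1, ] <- 2 * TA[3, ]
  A2 <- suppressWarnings(cluster_trait_affiliation(TA, cm2))
  expect_equal(unname(A2[3, 1]), 1, tolerance = 1e-10)
  expect_error(cluster_trait_affiliation(TA[, 1:2], cm), "3 ordination axes")
})

test_that("affiliation is invariant to cluster relabeling up to columns", {
  dat <- simulate_dataset(synthetic_scenario(n_species = 30), seed = 8)
  ord <- pcoa(jaccard_distance(dat$habitat))
  TA <- suppressWarnings(trait_axis_correlation(dat$habitat, ord))
  cm <- kmeans_cluster(ord$scores, 3, restarts = 20, seed = 2)
  A <- suppressWarnings(cluster_trait_affiliation(TA, cm))
  perm <- c(3, 1, 2)
  cmp <- cm
  cmp$centers <- cm$centers[perm, ]
  cmp$assignments <- match(cm$assignments, perm)
  Ap <- suppressWarnings(cluster_trait_affiliation(TA, cmp))
  expect_equal(unname(Ap), unname(A[, perm]))
})

test_that("name_clusters ranks descriptors by affiliation", {
  A <- matrix(c(0.9, -0.2, 0.1, 0.8, 0.2, -0.5), 3, 2,
              dimnames = list(c("sand", "rock", "veg"), c("c1", "c2")))
  nm <- name_clusters(A, top_n = 2)
  expect_equal(names(nm$c1), c("sand", "veg"))
  expect_equal(names(nm$c2), c("sand", "rock"))
  expect_equal(names(name_clusters(A, top_n = 1)$c1), "sand")
  expect_warning(name_clusters(matrix(0, 2, 2,
                                      dimnames = list(c("a", "b"), NULL))),
                 "arbitrary")
})

test_that("GMM BIC identifies blob count and penalizes overfitting", {
  set.seed(13)
  X2 <- rbind(matrix(stats::rnorm(100, 0), 50, 2),
              matrix(stats::rnorm(100, 10), 50, 2))
  b2 <- gmm_bic_curve(X2, kmax = 5, n_init = 3, seed = 1)
  expect_equal(which.max(b2$bic), 2L)
  # a single blob never prefers two components
  X1 <- matrix(stats::rnorm(200), 100, 2)
  b1 <- gmm_bic_curve(X1, kmax = 3, n_init = 3, seed = 1)
  expect_gte(b1$bic[1], b1$bic[2])
  # degenerate tiny data exercises the missing-k warning path
  X0 <- matrix(c(0, 0, 0, 0, 1e-12, 0), 3, 2)
  expect_warning(b0 <- gmm_bic_curve(X0, kmax = 3, n_init = 2, seed = 1),
                 "degenerate")
  expect_true(anyNA(b0$bic))
})

test_that("full pipeline cluster recovery holds on a strong scenario", {
  hits <- 0
  aris <- numeric(10)
  for (s in 1:10) {
    dat <- simulate_dataset(synthetic_scenario(), seed = 1000 + s)
    ord <- pcoa(jaccard_distance(dat$habitat))
    cm <- kmeans_cluster(ord$scores, 4, restarts = 50, seed = s)
    aris[s] <- adjusted_rand_index(cm$assignments,
                                   dat$labels[names(cm$assignments)])
  }
  expect_gte(mean(aris), 0.9)
})
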