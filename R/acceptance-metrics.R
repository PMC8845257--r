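# Simulation-based calibration metrics. These back both the acceptance test
# suite and scripts/acceptance.R, so the numbers reported there are computed
# by exactly one code path.

#' Calibration of Blomberg's K under Brownian motion
#'
#' Simulates `n_sim` single traits by Brownian motion, each on its own
#' pure-birth tree of `n_tips` tips, and returns the K values plus the
#' permutation p-values of the row-shuffle test applied to phylogenetically
#' unstructured (iid normal) traits on the same trees. Under Brownian motion
#' the mean K is calibrated to 1; under the iid null the p-values are
#' uniform.
#'
#' @param n_sim number of simulated datasets.
#' @param n_tips tips per tree.
#' @param n_perm permutations for the null p-values.
#' @param seed integer seed.
#' @return List with `K` (length `n_sim`) and `p_null` (length `n_sim`).
#' @export
calibrate_physignal <- function(n_sim = 500, n_tips = 60, n_perm = 199,
                                seed = NULL) {
  seeds <- spawn_seeds(seed, 3)
  tree_seeds <- spawn_seeds(seeds[1], n_sim)
  K <- numeric(n_sim)
  p_null <- numeric(n_sim)
  with_seed(seeds[2], {
    for (i in seq_len(n_sim)) {
      tree <- simulate_tree(n_tips, seed = tree_seeds[i])
      C <- phylo_vcv(tree)
      y_bm <- simulate_bm(tree, 1)
      K[i] <- physignal(y_bm, C, n_perm = 1, seed = 1)$K
      y_iid <- stats::rnorm(n_tips)
      p_null[i] <- physignal(y_iid, C, n_perm = n_perm, seed = i)$p
    }
  })
  list(K = K, p_null = p_null)
}

#' Type-I error of the phylogenetic PLS and RRPP MANOVA
#'
#' Runs both tests on data simulated under their null hypotheses --
#' independent Brownian-motion blocks for the PLS, random group labels on a
#' Brownian-motion response for the MANOVA -- and returns the p-values.
#'
#' @param n_sim simulated datasets per test.
#' @param n_tips tips per tree.
#' @param p,q block widths (ecology / morphology).
#' @param k_groups group count for the MANOVA null.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return List with numeric vectors `p_pls` and `p_manova`.
#' @export
type1_error_rates <- function(n_sim = 500, n_tips = 40, p = 3, q = 4,
                              k_groups = 3, n_perm = 999, seed = NULL) {
  seeds <- spawn_seeds(seed, 2)
  tree_seeds <- spawn_seeds(seeds[1], n_sim)
  p_pls <- numeric(n_sim)
  p_manova <- numeric(n_sim)
  with_seed(seeds[2], {
    for (i in seq_len(n_sim)) {
      tree <- simulate_tree(n_tips, seed = tree_seeds[i])
      C <- phylo_vcv(tree)
      X <- simulate_bm(tree, p)
      Y <- simulate_bm(tree, q)
      p_pls[i] <- phylo_pls(X, Y, C, n_perm = n_perm, seed = i)$p
      g <- sample(rep_len(seq_len(k_groups), n_tips))
      p_manova[i] <- rrpp_manova(Y, g, C, n_perm = n_perm,
                                 seed = i)$table$p[1]
    }
  })
  list(p_pls = p_pls, p_manova = p_manova)
}

#' Cluster-number recovery, k-means accuracy and MANOVA power
#'
#' Runs the ecospace and distinctiveness stages of the pipeline on `n_sim`
#' independent draws of a strong synthetic scenario and summarizes per-seed
#' outcomes: the cluster number selected by the BIC plateau rule, the
#' adjusted Rand index of k-means at the true k, and the RRPP MANOVA p-value
#' for eco-projected morphology across the k-means clusters.
#'
#' @param n_sim number of seeds.
#' @param scn scenario; defaults to the strong study-shaped scenario.
#' @param kmax,eps cluster-number scan parameters.
#' @param n_perm permutations for PLS/MANOVA.
#' @param seed integer seed.
#' @return Data frame with columns `k_selected`, `ari`, `p_manova`.
#' @export
recovery_rates <- function(n_sim = 100, scn = synthetic_scenario(),
                           kmax = 9, eps = 0.05, n_perm = 499, seed = NULL) {
  seeds <- spawn_seeds(seed, n_sim)
  out <- data.frame(k_selected = integer(n_sim), ari = numeric(n_sim),
                    p_manova = numeric(n_sim))
  for (i in seq_len(n_sim)) {
    dat <- simulate_dataset(scn, seed = seeds[i])
    ord <- pcoa(jaccard_distance(dat$habitat))
    b <- suppressWarnings(gmm_bic_curve(ord$scores, kmax = kmax,
                                        models = "spherical", n_init = 5,
                                        seed = seeds[i]))
    out$k_selected[i] <- select_k_plateau(b, eps = eps)
    cm <- kmeans_cluster(ord$scores, scn$k_true, restarts = 50,
                         seed = seeds[i])
    out$ari[i] <- adjusted_rand_index(cm$assignments,
                                      dat$labels[names(cm$assignments)])
    C <- phylo_vcv(dat$tree)
    sc <- size_correct(dat$traits)
    pls <- phylo_pls(ord$scores, unclass(sc), C, n_perm = n_perm,
                     seed = seeds[i])
    Yc <- sweep(unclass(sc), 2, drop(phylo_gls_mean(unclass(sc), C)))
    eco <- Yc %*% pls$y_rotation
    out$p_manova[i] <- rrpp_manova(eco, cm$assignments, C, n_perm = n_perm,
                                   seed = seeds[i])$table$p[1]
  }
  out
}
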