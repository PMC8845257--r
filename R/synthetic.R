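# Synthetic-data generators mirroring the structure the analysis assumes: a
# pure-birth ultrametric tree, k latent ecological clusters emitting Bernoulli
# microhabitat profiles, and log-scale morphology built from an isometric size
# component, Brownian motion along the tree, cluster-linked mean shifts on a
# subset of traits, and observation noise.

#' Describe a synthetic scenario
#'
#' Defaults copy the matrix shapes of a realistic order-wide study: 61
#' species, 12 binary microhabitat descriptors, 36 log-scale traits, 4 latent
#' ecological clusters. Cluster Bernoulli profiles put probability 0.9 on a
#' cluster's characteristic descriptors and 0.05 elsewhere (sand, vegetation,
#' hard-soil and rock syndromes). `effect_size` is the SD of cluster mean
#' shifts in units of the Brownian-motion SD over the tree depth;
#' `size_sd = 0.5` spreads species sizes over roughly an e^3-fold range
#' (comparable to a 22-158 mm body-length span on the log scale) and
#' `noise_sd = 0.05` is ~5% measurement error on the log scale.
#'
#' @param n_species,n_descriptors,n_traits,k_true dimensions.
#' @param cluster_profiles optional k x m Bernoulli probability matrix.
#' @param size_sd SD of the per-species isometric size component.
#' @param bm_rate Brownian-motion rate (variance per unit branch length).
#' @param effect_size cluster mean-shift magnitude in BM-SD units.
#' @param shifted_traits indices of traits receiving cluster shifts; `NULL`
#'   shifts the first `min(10, n_traits)` traits.
#' @param noise_sd observation noise SD.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_species = 61, n_descriptors = 12,
                               k_true = 4, cluster_profiles = NULL,
                               n_traits = 36, size_sd = 0.5, bm_rate = 1,
                               effect_size = 2, shifted_traits = NULL,
                               noise_sd = 0.05) {
  if (is.null(shifted_traits)) shifted_traits <- seq_len(min(10, n_traits))
  if (is.null(cluster_profiles)) {
    cluster_profiles <- default_cluster_profiles(k_true, n_descriptors)
  }
  cluster_profiles <- as.matrix(cluster_profiles)
  if (nrow(cluster_profiles) != k_true || ncol(cluster_profiles) != n_descriptors)
    stop("cluster_profiles must be k_true x n_descriptors")
  if (any(cluster_profiles < 0 | cluster_profiles > 1))
    stop("Bernoulli probabilities must lie in [0, 1]")
  if (any(rowSums(cluster_profiles) == 0))
    stop("a cluster profile of all zeros cannot generate valid species")
  if (min(n_species, n_descriptors, n_traits, k_true) < 1)
    stop("all dimensions must be positive")
  if (length(shifted_traits) > 0 && max(shifted_traits) > n_traits)
    stop("shifted_traits out of range")
  structure(list(n_species = n_species, n_descriptors = n_descriptors,
                 k_true = k_true, cluster_profiles = cluster_profiles,
                 n_traits = n_traits, size_sd = size_sd, bm_rate = bm_rate,
                 effect_size = effect_size, shifted_traits = shifted_traits,
                 noise_sd = noise_sd),
            class = "synthetic_scenario")
}

# Four-syndrome default: each cluster has 2-3 characteristic descriptors at
# probability 0.9 against a 0.05 background; extra descriptors (m > 12) stay
# at background for every cluster.
default_cluster_profiles <- function(k, m) {
  prof <- matrix(0.05, k, m)
  core <- list(c(1, 2), c(3, 4, 5), c(2, 6, 7), c(8, 9))
  for (c in seq_len(k)) {
    idx <- core[[(c - 1) %% length(core) + 1]]
    prof[c, idx[idx <= m]] <- 0.9
  }
  prof
}

#' Simulate a pure-birth ultrametric tree
#'
#' Yule (constant-rate speciation, no extinction) topology, then Grafen
#' branch lengths so the tree is ultrametric with depth 1 -- the same
#' convention applied to empirical topology-only trees.
#'
#' @param n number of tips (at least 3). Tips are labeled `sp01, sp02, ...`.
#' @param seed integer seed.
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n, seed = NULL) {
  if (n < 3) stop("need at least three tips")
  tree <- with_seed(seed, ape::rphylo(n, birth = 1, death = 0))
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  grafen_branch_lengths(tree)
}

#' Simulate clustered binary microhabitat profiles
#'
#' Assigns species to the scenario's latent clusters in near-equal numbers and
#' draws each descriptor from the cluster's Bernoulli profile; all-zero rows
#' are redrawn so the output satisfies the loader's invariant.
#'
#' @param scn a [synthetic_scenario()].
#' @param species_ids optional species labels (default `sp001...`).
#' @param seed integer seed.
#' @return List with `habitat` (a [microhabitat_matrix()]) and `labels`
#'   (true cluster assignment per species).
#' @export
simulate_microhabitat <- function(scn, species_ids = NULL, seed = NULL) {
  n <- scn$n_species; m <- scn$n_descriptors
  if (is.null(species_ids)) species_ids <- sprintf("sp%03d", seq_len(n))
  with_seed(seed, {
    labels <- sample(rep_len(seq_len(scn$k_true), n))
    vals <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      repeat {
        row <- stats::rbinom(m, 1, scn$cluster_profiles[labels[i], ])
        if (sum(row) > 0) break
      }
      vals[i, ] <- row
    }
    habitat <- microhabitat_matrix(
      vals, species_ids = species_ids,
      descriptor_names = sprintf("descriptor_%02d", seq_len(m)))
    list(habitat = habitat, labels = stats::setNames(labels, species_ids))
  })
}

#' Simulate Brownian-motion traits on a tree
#'
#' Increments are drawn pre-order along each branch with variance
#' `rate * branch length` and accumulated from a root value of zero, which is
#' exact for ultrametric and non-ultrametric trees alike.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param n_traits number of independent traits to simulate.
#' @param rate Brownian-motion rate (variance per unit branch length).
#' @return Ntip x `n_traits` matrix of tip states in tip-label order.
#' @export
simulate_bm <- function(tree, n_traits, rate = 1) {
  n <- ape::Ntip(tree)
  n_nodes <- n + tree$Nnode
  states <- matrix(0, n_nodes, n_traits)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[e, 1]; child <- pre$edge[e, 2]
    states[child, ] <- states[parent, ] +
      stats::rnorm(n_traits, 0, sqrt(rate * pre$edge.length[e]))
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate log-scale morphology on a tree
#'
#' Trait `j` of species `i` is
#' `size_i + BM_ij + shift[label_i, j] + noise`, with the size component
#' shared across all traits (isometry), Brownian motion run along the tree at
#' rate `bm_rate`, and cluster shifts drawn once per (cluster, shifted trait)
#' from `N(0, (effect_size * BM-SD)^2)`.
#'
#' @param tree an ultrametric tree whose tips name the species.
#' @param labels true cluster labels aligned to the tips.
#' @param scn a [synthetic_scenario()].
#' @param seed integer seed.
#' @return A stage `"log"` [trait_table()] in tip order, with attributes
#'   `size` (the generating size vector) and `shifts` (k x n_traits matrix).
#' @export
simulate_morphology <- function(tree, labels, scn, seed = NULL) {
  n <- ape::Ntip(tree)
  if (length(labels) != n) stop("labels must align to the tree tips")
  labels <- labels[tree$tip.label]
  if (anyNA(labels)) stop("labels must be named by tip label")
  with_seed(seed, {
    size <- stats::rnorm(n, 0, scn$size_sd)
    bm <- simulate_bm(tree, scn$n_traits, scn$bm_rate)
    depth <- max(ape::node.depth.edgelength(tree))
    shift_sd <- scn$effect_size * sqrt(scn$bm_rate * depth)
    shifts <- matrix(0, scn$k_true, scn$n_traits)
    if (length(scn$shifted_traits) > 0 && scn$effect_size > 0)
      shifts[, scn$shifted_traits] <-
        stats::rnorm(scn$k_true * length(scn$shifted_traits), 0, shift_sd)
    noise <- matrix(stats::rnorm(n * scn$n_traits, 0, scn$noise_sd),
                    n, scn$n_traits)
    vals <- size + bm + shifts[labels, , drop = FALSE] + noise
    out <- trait_table(vals, species_ids = tree$tip.label,
                       variable_names = sprintf("trait_%02d",
                                                seq_len(scn$n_traits)),
                       stage = "log")
    attr(out, "size") <- stats::setNames(size, tree$tip.label)
    attr(out, "shifts") <- shifts
    out
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: tree, microhabitat matrix and morphology from one
#' scenario and one seed (sub-seeds are spawned deterministically).
#'
#' @param scn a [synthetic_scenario()].
#' @param seed integer seed.
#' @return List with `tree`, `habitat`, `traits` (stage `"log"`), `labels`.
#' @export
simulate_dataset <- function(scn, seed = NULL) {
  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max, 1), 3)
  tree <- simulate_tree(scn$n_species, seed = seeds[1])
  eco <- simulate_microhabitat(scn, species_ids = tree$tip.label,
                               seed = seeds[2])
  traits <- simulate_morphology(tree, eco$labels, scn, seed = seeds[3])
  list(tree = tree, habitat = eco$habitat, traits = traits,
       labels = eco$labels)
}
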