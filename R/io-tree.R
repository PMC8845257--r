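# Phylogeny utilities. Trees are `ape::phylo` objects throughout; polytomies
# are kept as true multifurcations (the Brownian-motion covariance is well
# defined for them, so nothing forces a zero-branch resolution).

#' Read a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that additionally rejects duplicate
#' tip labels. Branch lengths are optional: trees can be topology-only and
#' receive lengths later via [grafen_branch_lengths()].
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick file ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable Newick file ", path)
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Assign Grafen branch lengths
#'
#' Gives every internal node a height above the tips of
#' `((descendant tips - 1) / (n - 1))^rho`, with tips at height zero, and sets
#' each branch length to the height difference between its endpoints. The
#' result is ultrametric with root-to-tip depth exactly 1, which is the
#' conventional way of equipping a topology-only comparative tree with branch
#' lengths.
#'
#' @param tree an `ape::phylo` tree (any or no branch lengths).
#' @param rho positive power applied to the relative heights; 1 keeps heights
#'   proportional to clade size.
#' @return The tree with new `edge.length`.
#' @export
grafen_branch_lengths <- function(tree, rho = 1) {
  n <- ape::Ntip(tree)
  if (n < 2) stop("need at least two tips")
  if (rho <= 0) stop("rho must be positive")
  n_nodes <- n + tree$Nnode
  ndesc <- integer(n_nodes)
  ndesc[seq_len(n)] <- 1L
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    ndesc[post$edge[e, 1]] <- ndesc[post$edge[e, 1]] + ndesc[post$edge[e, 2]]
  }
  height <- numeric(n_nodes)
  internal <- (n + 1):n_nodes
  height[internal] <- ((ndesc[internal] - 1) / (n - 1))^rho
  tree$edge.length <- height[tree$edge[, 1]] - height[tree$edge[, 2]]
  tree
}

#' Brownian-motion covariance matrix of a tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds tip depths. Under Brownian motion this is the expected
#' covariance structure of a trait across tips, the `C` matrix behind every
#' GLS operation in the package.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return A symmetric positive-semidefinite matrix in tip-label order.
#' @export
phylo_vcv <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and complete")
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label]
}

#' Align trait, microhabitat and tree inputs to one species order
#'
#' Takes any combination of a [trait_table()], a [microhabitat_matrix()] and a
#' tree (named `traits`, `habitat`, `tree`), intersects their species sets,
#' prunes the tree to the intersection and reorders tables to the tree's tip
#' order (or to the first table's order when no tree is given). Dropping
#' species raises a warning, never an error; an empty intersection errors.
#'
#' @param traits optional [trait_table()].
#' @param habitat optional [microhabitat_matrix()].
#' @param tree optional `ape::phylo`.
#' @return A list with the supplied components aligned, plus `species`.
#' @export
align_species <- function(traits = NULL, habitat = NULL, tree = NULL) {
  sets <- list()
  if (!is.null(traits)) sets$traits <- rownames(traits)
  if (!is.null(habitat)) sets$habitat <- rownames(habitat)
  if (!is.null(tree)) sets$tree <- trimws(tree$tip.label)
  if (length(sets) < 2) stop("need at least two objects to align")
  common <- Reduce(intersect, sets)
  if (length(common) == 0) stop("no species shared across inputs")
  dropped <- unique(unlist(lapply(sets, setdiff, y = common)))
  if (length(dropped) > 0)
    warning(length(dropped), " species dropped during alignment: ",
            paste(utils::head(dropped, 8), collapse = ", "),
            if (length(dropped) > 8) ", ..." else "")
  if (!is.null(tree)) {
    tree$tip.label <- trimws(tree$tip.label)
    if (length(common) < ape::Ntip(tree))
      tree <- ape::keep.tip(tree, common)
    order <- tree$tip.label
  } else {
    order <- sets[[1]][sets[[1]] %in% common]
  }
  out <- list(species = order)
  if (!is.null(traits))
    out$traits <- trait_table(unclass(traits)[order, , drop = FALSE],
                              stage = trait_stage(traits))
  if (!is.null(habitat))
    out$habitat <- microhabitat_matrix(unclass(habitat)[order, , drop = FALSE])
  if (!is.null(tree)) out$tree <- tree
  out
}
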