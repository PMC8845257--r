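# Ecospace construction: Jaccard distances between binary microhabitat
# profiles, principal coordinates, cluster-number selection and k-means, then
# the two matrix correlations that relate descriptors to clusters.

#' Jaccard distances between species' microhabitat profiles
#'
#' `d(i, j) = 1 - shared presences / union of presences`. All-zero rows cannot
#' occur (rejected at load), so the ratio is always defined.
#'
#' @param M a [microhabitat_matrix()].
#' @return Symmetric n x n distance matrix with zero diagonal, entries in
#'   `[0, 1]`, class `dist_matrix`.
#' @export
jaccard_distance <- function(M) {
  if (!inherits(M, "microhabitat_matrix"))
    M <- microhabitat_matrix(M)
  d <- as.matrix(vegan::vegdist(unclass(M), method = "jaccard", binary = TRUE))
  dimnames(d) <- list(rownames(M), rownames(M))
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

#' Principal coordinates analysis
#'
#' Metric embedding of a distance matrix: Gower double-centering
#' `B = -1/2 * J D^2 J` followed by an eigendecomposition. Axes with
#' eigenvalue above `tol * max(eigenvalue)` are retained; coordinates are
#' eigenvectors scaled by the square root of their eigenvalue, so Euclidean
#' distances between retained scores approximate (and for Euclidean-embeddable
#' input reproduce) the input distances. Non-Euclidean distances such as
#' Jaccard typically yield more positive axes than the number of descriptors.
#'
#' @param D square distance matrix (e.g. from [jaccard_distance()]).
#' @param tol relative eigenvalue tolerance for axis retention.
#' @return An `ordination`: list with `scores` (n x A), `eigenvalues`,
#'   `prop_explained` (relative to the positive eigenvalues) and `species`.
#' @export
pcoa <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0))
    stop("D must be a symmetric distance matrix with zero diagonal")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- eig$values > tol * max(eig$values)
  if (!any(keep)) stop("no positive eigenvalues: degenerate distance matrix")
  lambda <- eig$values[keep]
  scores <- eig$vectors[, keep, drop = FALSE] %*% diag(sqrt(lambda),
                                                       length(lambda))
  rownames(scores) <- rownames(D)
  colnames(scores) <- paste0("Axis", seq_along(lambda))
  structure(list(scores = scores, eigenvalues = lambda,
                 prop_explained = lambda / sum(eig$values[eig$values > 0]),
                 species = rownames(D)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("PCoA ordination: %d species, %d retained axes\n",
              nrow(x$scores), ncol(x$scores)))
  cat("first axes explain:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 5)),
             collapse = ", "), "\n")
  invisible(x)
}

#' Select the cluster number at the first BIC plateau
#'
#' Scans the BIC curve (higher is better) for the smallest `k` whose gain to
#' `k + 1` falls below `eps` times the curve's range -- the first k preceding
#' a plateau. When no plateau exists (the curve keeps climbing steeply) the
#' argmax is returned instead.
#'
#' @param b a `bic_curve` from [gmm_bic_curve()], or a numeric vector of BIC
#'   values indexed by k.
#' @param eps plateau threshold as a fraction of the BIC range.
#' @return Selected integer `k`.
#' @export
select_k_plateau <- function(b, eps = 0.05) {
  bic <- if (inherits(b, "bic_curve")) b$bic else as.numeric(b)
  k_values <- if (inherits(b, "bic_curve")) b$k else seq_along(bic)
  ok <- is.finite(bic)
  bic <- bic[ok]; k_values <- k_values[ok]
  if (length(bic) < 3) stop("BIC curve needs at least three entries")
  if (eps <= 0 || eps >= 1) stop("eps must lie in (0, 1)")
  span <- max(bic) - min(bic)
  gains <- diff(bic)
  plateau <- which(gains < eps * span)
  if (length(plateau) > 0) return(k_values[plateau[1]])
  k_values[which.max(bic)]
}

#' k-means clustering with k-means++ starts
#'
#' Lloyd's algorithm started from k-means++ seeds, best of `restarts` runs by
#' within-cluster sum of squares; deterministic given `seed`.
#'
#' @param X numeric matrix of coordinates (typically PCoA scores).
#' @param k number of clusters.
#' @param restarts independent restarts.
#' @param seed integer seed.
#' @return A `cluster_model`: list with `k`, `assignments` (named), `centers`,
#'   `inertia`.
#' @export
kmeans_cluster <- function(X, k, restarts = 100, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must lie in 1..n")
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_init(X, k)
      res <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = centers,
                                       iter.max = 100, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(res) || any(res$size == 0)) next
      if (is.null(best) || res$tot.withinss < best$tot.withinss) best <- res
    }
    best
  })
  if (is.null(fit)) stop("k-means failed: empty cluster in every restart")
  assignments <- fit$cluster
  names(assignments) <- rownames(X)
  structure(list(k = k, assignments = assignments, centers = fit$centers,
                 inertia = fit$tot.withinss),
            class = "cluster_model")
}

# k-means++ seeding: first center uniform, later centers drawn with
# probability proportional to squared distance from the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                         byrow = TRUE))^2))
    }
  }
  # tiny jitter resolves duplicate seed points on discrete data
  centers + stats::rnorm(length(centers), 0, 1e-10)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means model: k = %d, inertia = %.4f\n", x$k, x$inertia))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Correlate microhabitat descriptors with ordination axes
#'
#' Entry (j, a) is the correlation of binary descriptor j with PCoA axis a
#' across species. Constant descriptor columns get correlation 0 with a
#' warning rather than NA.
#'
#' @param M a [microhabitat_matrix()].
#' @param ord an [pcoa()] ordination on the same species, same order.
#' @param method `"pearson"` or `"spearman"`.
#' @return m x A correlation matrix.
#' @export
trait_axis_correlation <- function(M, ord, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(rownames(M), rownames(ord$scores)))
    stop("species order of habitat matrix and ordination differ")
  const <- apply(unclass(M), 2, function(col) stats::sd(col) == 0)
  out <- suppressWarnings(stats::cor(unclass(M), ord$scores, method = method))
  if (any(const)) {
    warning("constant descriptor column(s) set to zero correlation: ",
            paste(colnames(M)[const], collapse = ", "))
    out[const, ] <- 0
  }
  out
}

#' Correlate descriptor axis-profiles with cluster centers
#'
#' Second matrix correlation of the ecospace characterization: each
#' descriptor's vector of axis correlations (a row of
#' [trait_axis_correlation()]'s output) is correlated, across the A ordination
#' axes, with each k-means center's coordinates. High affiliation means the
#' descriptor varies along the same ecospace direction in which the cluster
#' sits.
#'
#' @param TA m x A matrix from [trait_axis_correlation()].
#' @param model a [kmeans_cluster()] model fitted in the same A-dimensional
#'   ordination space.
#' @param method `"pearson"` or `"spearman"`.
#' @return m descriptors x k clusters affiliation matrix.
#' @export
cluster_trait_affiliation <- function(TA, model,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(TA) < 3)
    stop("affiliation needs at least 3 ordination axes to correlate over")
  if (ncol(TA) != ncol(model$centers))
    stop("descriptor profiles and cluster centers live in different spaces")
  out <- suppressWarnings(stats::cor(t(TA), t(model$centers), method = method))
  flat <- apply(TA, 1, function(row) stats::sd(row) == 0)
  if (any(flat)) {
    warning("descriptor(s) with a flat axis profile set to zero affiliation: ",
            paste(rownames(TA)[flat], collapse = ", "))
    out[flat, ] <- 0
  }
  dimnames(out) <- list(rownames(TA), paste0("cluster", seq_len(model$k)))
  out
}

#' Rank descriptors per cluster by affiliation
#'
#' Produces, for each cluster, its descriptors sorted by decreasing
#' affiliation -- the basis on which a user names clusters (e.g. a cluster
#' whose top descriptors are "loose sand" and "dug burrow" earns a
#' sand-dweller name). Naming itself stays with the user.
#'
#' @param A affiliation matrix from [cluster_trait_affiliation()].
#' @param top_n how many descriptors to keep per cluster.
#' @return Named list (one element per cluster) of named numeric vectors.
#' @export
name_clusters <- function(A, top_n = nrow(A)) {
  if (all(A == 0)) warning("all affiliations are zero; ranking is arbitrary")
  out <- lapply(seq_len(ncol(A)), function(cl) {
    ord <- order(A[, cl], decreasing = TRUE)
    utils::head(stats::setNames(A[ord, cl], rownames(A)[ord]), top_n)
  })
  names(out) <- colnames(A)
  out
}
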