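# Phylogenetically informed inference under a Brownian-motion covariance
# matrix C: GLS means and whitening, two-block phylogenetic PLS, GLS MANOVA
# with randomized residual permutation (RRPP), distance-based pairwise group
# tests, and Blomberg's K phylogenetic signal (univariate and multivariate).
# All permutation p-values use the +1 convention, so the smallest attainable
# p is 1/(n_perm + 1).

#' Generalized least-squares mean
#'
#' Phylogenetic (GLS) estimate of the root state / grand mean of each column:
#' `a = (1' C^-1 1)^-1 1' C^-1 Y`. With `C = I` this is the ordinary column
#' mean.
#'
#' @param Y n x q numeric matrix (a vector is treated as one column).
#' @param C n x n phylogenetic covariance from [phylo_vcv()].
#' @return Row vector (1 x q) of GLS means.
#' @export
phylo_gls_mean <- function(Y, C) {
  Y <- as.matrix(Y)
  w <- solve(C, rep(1, nrow(C)))
  matrix(colSums(w * Y) / sum(w), 1, ncol(Y),
         dimnames = list(NULL, colnames(Y)))
}

#' Phylogenetic whitening transform
#'
#' Centers `Y` at its GLS mean and premultiplies by the symmetric inverse
#' square root of `C`, so the transformed rows have identity error covariance
#' under Brownian motion. Near-singular `C` receives a ridge of 1e-8 with a
#' warning.
#'
#' @inheritParams phylo_gls_mean
#' @return Transformed n x q matrix.
#' @export
phylo_transform <- function(Y, C) {
  Y <- as.matrix(Y)
  a <- phylo_gls_mean(Y, C)
  P <- mat_inv_sqrt(C)
  out <- P %*% (Y - rep(1, nrow(Y)) %*% a)
  dimnames(out) <- dimnames(Y)
  out
}

#' Two-block phylogenetic partial least squares
#'
#' Tests and quantifies the association between two multivariate blocks
#' (here: ecology as PCoA axes, morphology as size-corrected traits) observed
#' on the tips of a phylogeny. The GLS cross-covariance
#' `R12 = X~' C^-1 Y~ / (n - 1)` (blocks centered at their GLS means) is
#' decomposed by SVD; the first pair of singular vectors gives the block
#' loadings, scores are the whitened blocks projected on them, and `r` is the
#' Pearson correlation of the two score vectors. Significance comes from
#' permuting the rows of the whitened Y block -- the exchangeable units under
#' GLS -- and recomputing `r` each time.
#'
#' @param X n x p block (ecology).
#' @param Y n x q block (morphology).
#' @param C phylogenetic covariance aligned to the rows of both blocks.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return A `pls_result`: list with `r`, `z`, `p`, unit-norm `x_loadings` /
#'   `y_loadings` (first pair), full rotation matrices `x_rotation` /
#'   `y_rotation`, `x_scores`, `y_scores`, `d` (singular values), `n_perm`.
#' @export
phylo_pls <- function(X, Y, C, n_perm = 10000, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n || nrow(C) != n) stop("X, Y and C must agree in rows")
  if (n <= 2) stop("need more than two species")
  Xt <- phylo_transform(X, C)
  Yt <- phylo_transform(Y, C)
  sv <- svd(crossprod(Xt, Yt) / (n - 1))
  u1 <- sv$u[, 1]; v1 <- sv$v[, 1]
  xs <- drop(Xt %*% u1); ys <- drop(Yt %*% v1)
  r_obs <- stats::cor(xs, ys)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      Yp <- Yt[sample.int(n), , drop = FALSE]
      s <- svd(crossprod(Xt, Yp) / (n - 1), nu = 1, nv = 1)
      stats::cor(drop(Xt %*% s$u), drop(Yp %*% s$v))
    }, numeric(1))
  })
  p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  z <- (r_obs - mean(r_perm)) / stats::sd(r_perm)
  structure(list(r = r_obs, z = z, p = p,
                 x_loadings = u1, y_loadings = v1,
                 x_rotation = sv$u, y_rotation = sv$v, d = sv$d,
                 x_scores = xs, y_scores = ys, n_perm = n_perm),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic two-block PLS: r = %.4f, Z = %.3f, p = %.4g (%d permutations)\n",
    x$r, x$z, x$p, x$n_perm))
  invisible(x)
}

#' Blomberg's K phylogenetic signal
#'
#' Ratio of the observed trait variance partitioning to that expected under
#' Brownian motion on the supplied tree; K is calibrated so that BM data give
#' K near 1, while values below 1 indicate less phylogenetic signal than BM.
#' For `q > 1` columns the traces generalize the univariate statistic to a
#' single multivariate K. Significance is assessed by shuffling species rows.
#' A star phylogeny (no shared history) leaves K undefined and errors.
#'
#' @param y n x q trait matrix (vector accepted for univariate K).
#' @param C phylogenetic covariance.
#' @param n_perm permutations for the significance test.
#' @param seed integer seed.
#' @return A `k_result`: list with `K`, `p`, `n_perm`, `scope`.
#' @export
physignal <- function(y, C, n_perm = 999, seed = NULL) {
  Y <- as.matrix(y)
  n <- nrow(Y)
  if (nrow(C) != n) stop("C must match the number of species")
  off <- C[upper.tri(C)]
  if (all(abs(off) < 1e-12))
    stop("star phylogeny: K is undefined (no shared branch lengths)")
  Cinv <- solve(C)
  w <- rowSums(Cinv)
  sw <- sum(w)
  expected <- (sum(diag(C)) - n / sw) / (n - 1)
  k_stat <- function(Ym) {
    a <- colSums(w * Ym) / sw
    Yc <- Ym - rep(1, n) %*% t(a)
    num <- sum(Yc * Yc)
    den <- sum(Yc * (Cinv %*% Yc))
    (num / den) / expected
  }
  K_obs <- k_stat(Y)
  K_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) k_stat(Y[sample.int(n), , drop = FALSE]),
           numeric(1))
  })
  p <- (sum(K_perm >= K_obs) + 1) / (n_perm + 1)
  structure(list(K = K_obs, p = p, n_perm = n_perm,
                 scope = if (ncol(Y) > 1) "multivariate" else "univariate"),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("Blomberg's K (%s): K = %.4f, p = %.4g (%d permutations)\n",
              x$scope, x$K, x$p, x$n_perm))
  invisible(x)
}

#' GLS MANOVA with randomized residual permutation
#'
#' Fits, on the phylogenetically whitened scale, the full linear model
#' `Y ~ groups` against the intercept-only reduced model. Sums of squares are
#' traces of residual cross-product matrices; the group effect is tested by
#' RRPP: reduced-model residual rows are shuffled, added back to the
#' reduced-model fit, and the pseudo-F recomputed.
#'
#' @param Y n x q response matrix (e.g. eco-projected morphology).
#' @param groups length-n factor/vector of group labels, each level with at
#'   least two members.
#' @param C phylogenetic covariance; use `diag(n)` for a non-phylogenetic
#'   analysis.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return An `rrpp_manova_fit` with the ANOVA-style table (`$table`: Df, SS,
#'   MS, Rsq, F, Z, p for the group term plus residual and total rows) and the
#'   internals needed by [pairwise_group_tests()].
#' @export
rrpp_manova <- function(Y, groups, C = NULL, n_perm = 10000, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  groups <- factor(groups)
  if (length(groups) != n) stop("groups must label every row of Y")
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two members")
  if (is.null(C)) C <- diag(n)
  P <- mat_inv_sqrt(C)
  Yt <- P %*% Y
  Xf <- P %*% stats::model.matrix(~groups)
  X0 <- P %*% matrix(1, n, 1)
  Qf <- qr.Q(qr(Xf))[, seq_len(qr(Xf)$rank), drop = FALSE]
  Q0 <- qr.Q(qr(X0))[, 1, drop = FALSE]
  total_ss <- function(R) sum(R * R)
  R0 <- Yt - Q0 %*% crossprod(Q0, Yt)      # reduced-model residuals
  fitted0 <- Yt - R0
  rss0 <- total_ss(R0)
  rssf <- rss0 - (total_ss(crossprod(Qf, Yt)) - total_ss(crossprod(Q0, Yt)))
  df_term <- nlevels(groups) - 1
  df_resid <- n - nlevels(groups)
  ss_term <- rss0 - rssf
  F_obs <- (ss_term / df_term) / (rssf / df_resid)
  # under permutation Y* = fitted0 + R0[perm, ]; since fitted0 lies in both
  # model spaces, RSS(Y*) only involves the permuted residual block
  perm_idx <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  })
  S <- total_ss(R0)  # invariant under row permutation
  F_perm <- vapply(seq_len(n_perm), function(i) {
    Rp <- R0[perm_idx[i, ], , drop = FALSE]
    rss0_p <- S - total_ss(crossprod(Q0, Rp))
    rssf_p <- S - total_ss(crossprod(Qf, Rp))
    ((rss0_p - rssf_p) / df_term) / (rssf_p / df_resid)
  }, numeric(1))
  p <- (sum(F_perm >= F_obs) + 1) / (n_perm + 1)
  z <- (F_obs - mean(F_perm)) / stats::sd(F_perm)
  table <- data.frame(
    Df = c(df_term, df_resid, n - 1),
    SS = c(ss_term, rssf, rss0),
    MS = c(ss_term / df_term, rssf / df_resid, NA),
    Rsq = c(ss_term / rss0, rssf / rss0, NA),
    F = c(F_obs, NA, NA),
    Z = c(z, NA, NA),
    p = c(p, NA, NA),
    row.names = c("groups", "Residuals", "Total"))
  stopifnot(abs(table$SS[1] + table$SS[2] - table$SS[3]) < 1e-8 * max(1, rss0))
  structure(list(table = table, groups = groups, Yt = Yt, P = P,
                 fitted0 = fitted0, R0 = R0, perm_idx = perm_idx,
                 n_perm = n_perm, F_perm = F_perm),
            class = "rrpp_manova_fit")
}

#' @export
print.rrpp_manova_fit <- function(x, ...) {
  cat("GLS MANOVA with randomized residual permutation\n")
  print(round(x$table, 4))
  invisible(x)
}

# GLS least-squares group means on the whitened scale mapped back to trait
# space: with cell-means design M, coefficients solve the whitened normal
# equations and are already expressed in original trait units.
gls_group_means <- function(fit, Yt = fit$Yt) {
  Xm <- fit$P %*% stats::model.matrix(~0 + fit$groups)
  B <- solve(crossprod(Xm), crossprod(Xm, Yt))
  rownames(B) <- levels(fit$groups)
  B
}

#' Pairwise distances between group LS means, RRPP-tested
#'
#' Euclidean distances between the GLS least-squares means of every group
#' pair, with null distributions built from the same reduced-model residual
#' permutations stored in the fitted MANOVA, so the global and pairwise tests
#' share one permutation stream.
#'
#' @param fit an [rrpp_manova()] result.
#' @return A `pairwise_result` data frame: group pair, distance `d`,
#'   effect size `Z`, permutation p-value.
#' @export
pairwise_group_tests <- function(fit) {
  lev <- levels(fit$groups)
  pairs <- utils::combn(lev, 2)
  obs_means <- gls_group_means(fit)
  pair_d <- function(M) {
    vapply(seq_len(ncol(pairs)), function(j)
      sqrt(sum((M[pairs[1, j], ] - M[pairs[2, j], ])^2)), numeric(1))
  }
  d_obs <- pair_d(obs_means)
  n_perm <- fit$n_perm
  d_perm <- matrix(0, n_perm, ncol(pairs))
  for (i in seq_len(n_perm)) {
    Ystar <- fit$fitted0 + fit$R0[fit$perm_idx[i, ], , drop = FALSE]
    d_perm[i, ] <- pair_d(gls_group_means(fit, Ystar))
  }
  p <- (colSums(sweep(d_perm, 2, d_obs, ">=")) + 1) / (n_perm + 1)
  z <- (d_obs - colMeans(d_perm)) / apply(d_perm, 2, stats::sd)
  structure(data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                       d = d_obs, Z = z, p = p,
                       stringsAsFactors = FALSE),
            class = c("pairwise_result", "data.frame"))
}

#' Group means rotated to their principal components
#'
#' Rotates the GLS LS means to the principal components of the between-group
#' mean configuration (a rigid rotation, so inter-mean distances are
#' preserved) and returns per-group covariance matrices of the rotated
#' residuals -- the ingredients for drawing group ellipses downstream.
#'
#' @param Y n x q response matrix.
#' @param groups length-n group labels.
#' @param C phylogenetic covariance (`NULL` for identity).
#' @return List with `means` (k x min(q, k-1) rotated means), `rotation`,
#'   `group_cov` (named list of covariance matrices of rotated residuals).
#' @export
group_means_pca <- function(Y, groups, C = NULL) {
  Y <- as.matrix(Y)
  groups <- factor(groups)
  n <- nrow(Y)
  if (is.null(C)) C <- diag(n)
  P <- mat_inv_sqrt(C)
  Yt <- P %*% Y
  Xm <- P %*% stats::model.matrix(~0 + groups)
  B <- solve(crossprod(Xm), crossprod(Xm, Yt))
  rownames(B) <- levels(groups)
  pc <- stats::prcomp(B, center = TRUE)
  keep <- seq_len(min(ncol(Y), nlevels(groups) - 1))
  rot <- pc$rotation[, keep, drop = FALSE]
  means <- pc$x[, keep, drop = FALSE]
  resid <- Y - stats::model.matrix(~0 + groups) %*% B
  scores <- sweep(resid, 2, 0) %*% rot
  group_cov <- lapply(levels(groups), function(g)
    stats::cov(scores[groups == g, , drop = FALSE]))
  names(group_cov) <- levels(groups)
  list(means = means, rotation = rot, group_cov = group_cov)
}
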