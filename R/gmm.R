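# Gaussian-mixture fitting by EM for cluster-number selection. Three
# covariance families are supported, ordered from most to least parsimonious:
#   spherical - one variance shared by all clusters and dimensions
#   diagonal  - per-cluster, per-dimension variances
#   full      - per-cluster unrestricted covariance
# BIC is reported as 2*logLik - npar*log(n), so HIGHER is better and the
# cluster-number scan looks for the first k preceding a plateau of this curve.

gmm_n_params <- function(k, d, model) {
  base <- (k - 1) + k * d  # mixing weights + means
  base + switch(model,
                spherical = 1,
                diagonal  = k * d,
                full      = k * d * (d + 1) / 2)
}

# One EM fit from a k-means++ start. Returns NULL on degenerate fits: a
# component collapsing onto duplicate points (variance at the floor), a
# singular covariance, or an emptied component. Collapse is treated as
# failure rather than rescued, matching the maximum-likelihood convention of
# standard mixture software.
gmm_em_once <- function(X, k, model, centers = NULL, max_iter = 200,
                        reltol = 1e-8) {
  n <- nrow(X); d <- ncol(X)
  var_floor <- 1e-8 * mean(apply(X, 2, stats::var)) + 1e-12
  if (is.null(centers)) {
    centers <- kmeanspp_init(X, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers, iter.max = 30,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km) && !any(km$size == 0)) centers <- km$centers
  }
  mu <- centers
  w <- rep(1 / k, k)
  total_var <- mean(apply(X, 2, stats::var)) + var_floor
  sigma <- switch(model,
                  spherical = total_var,
                  diagonal  = matrix(total_var, k, d),
                  full      = replicate(k, diag(total_var, d),
                                        simplify = FALSE))
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    # E step: log densities per component
    logd <- matrix(0, n, k)
    for (j in seq_len(k)) {
      centered <- X - matrix(mu[j, ], n, d, byrow = TRUE)
      logd[, j] <- switch(model,
        spherical = -0.5 * (d * log(2 * pi * sigma) +
                              rowSums(centered^2) / sigma),
        diagonal = -0.5 * (d * log(2 * pi) + sum(log(sigma[j, ])) +
                             rowSums(sweep(centered^2, 2, sigma[j, ], "/"))),
        full = {
          ch <- tryCatch(chol(sigma[[j]]), error = function(e) NULL)
          if (is.null(ch)) return(NULL)
          z <- backsolve(ch, t(centered), transpose = TRUE)
          -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
        })
    }
    logd <- sweep(logd, 2, log(w), "+")
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    new_loglik <- sum(lse)
    resp <- exp(logd - lse)
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- sweep(crossprod(resp, X), 1, nk, "/")
    if (model == "spherical") {
      ss <- 0
      for (j in seq_len(k)) {
        centered <- X - matrix(mu[j, ], n, d, byrow = TRUE)
        ss <- ss + sum(resp[, j] * rowSums(centered^2))
      }
      sigma <- ss / (n * d)
      if (sigma <= var_floor) return(NULL)
    } else if (model == "diagonal") {
      for (j in seq_len(k)) {
        centered <- X - matrix(mu[j, ], n, d, byrow = TRUE)
        sigma[j, ] <- colSums(resp[, j] * centered^2) / nk[j]
      }
      if (any(sigma <= var_floor)) return(NULL)
    } else {
      for (j in seq_len(k)) {
        centered <- X - matrix(mu[j, ], n, d, byrow = TRUE)
        S <- crossprod(centered * resp[, j], centered) / nk[j]
        if (any(diag(S) <= var_floor) || rcond(S) < 1e-10) return(NULL)
        sigma[[j]] <- S
      }
    }
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) < reltol * (abs(loglik) + 1)) {
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  if (!is.finite(loglik)) return(NULL)
  list(loglik = loglik, weights = w, means = mu, model = model,
       assignments = max.col(resp))
}

#' BIC curve over candidate cluster numbers
#'
#' Fits Gaussian mixtures by EM for each `k` in `1..kmax` under each
#' covariance model and records the best BIC (`2*logLik - npar*log(n)`,
#' higher better) per k along with the winning model. Each (k, model) gets
#' one deterministic start from a Ward hierarchical partition -- nested
#' across k, which keeps the curve smooth -- plus `n_init` random k-means++
#' restarts. Degenerate fits (collapse onto duplicate points, singular
#' covariance) count as failures; a `k` where every model degenerates is
#' marked missing with a warning. Beware that on data containing exact
#' duplicate rows the `diagonal` and `full` families have unbounded
#' likelihood and are rejected or return arbitrary local optima; prefer
#' `models = "spherical"` there.
#'
#' @param X numeric matrix of observations (typically [pcoa()] scores); an
#'   `ordination` is accepted directly.
#' @param kmax largest cluster number to scan.
#' @param models subset of `c("spherical", "diagonal", "full")`.
#' @param n_init EM restarts per model and k.
#' @param seed integer seed.
#' @return A `bic_curve`: list with `k`, `bic`, `model` vectors.
#' @export
gmm_bic_curve <- function(X, kmax = 9,
                          models = c("spherical", "diagonal", "full"),
                          n_init = 5, seed = NULL) {
  if (inherits(X, "ordination")) X <- X$scores
  X <- as.matrix(X)
  if (kmax < 2) stop("kmax must be at least 2")
  if (nrow(X) < kmax) stop("need at least kmax observations")
  models <- match.arg(models, several.ok = TRUE)
  n <- nrow(X); d <- ncol(X)
  # deterministic hierarchical (Ward) partitions provide one nested, stable
  # start per k; random k-means++ restarts supplement it
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  res <- with_seed(seed, {
    bic <- rep(NA_real_, kmax)
    best_model <- rep(NA_character_, kmax)
    for (k in seq_len(kmax)) {
      part <- stats::cutree(hc, k)
      hc_centers <- t(vapply(seq_len(k), function(g)
        colMeans(X[part == g, , drop = FALSE]), numeric(d)))
      for (model in models) {
        for (init in seq_len(if (k == 1) 1 else n_init + 1)) {
          fit <- gmm_em_once(X, k, model,
                             centers = if (init == 1) hc_centers else NULL)
          if (is.null(fit)) next
          b <- 2 * fit$loglik - gmm_n_params(k, d, model) * log(n)
          if (is.na(bic[k]) || b > bic[k]) {
            bic[k] <- b
            best_model[k] <- model
          }
        }
      }
    }
    list(bic = bic, model = best_model)
  })
  if (anyNA(res$bic))
    warning("EM degenerate for k = ",
            paste(which(is.na(res$bic)), collapse = ", "),
            "; those k are marked missing")
  structure(list(k = seq_len(kmax), bic = res$bic, model = res$model),
            class = "bic_curve")
}

#' @export
print.bic_curve <- function(x, ...) {
  cat("BIC curve (higher is better):\n")
  print(data.frame(k = x$k, BIC = round(x$bic, 2), model = x$model),
        row.names = FALSE)
  invisible(x)
}
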