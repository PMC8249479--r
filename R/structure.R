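#' @name structure
#' @title PCA and model-based ancestry
#' @description
#' Population structure from an LD-pruned genotype matrix: PCA on
#' standardized dosages, and a K-cluster admixture model (per-individual
#' ancestry fractions Q, per-cluster allele frequencies F, binomial genotype
#' likelihood) fitted by a monotone multiplicative EM, with entry-masking
#' cross-validation to choose K.
NULL

# standardized dosage matrix: center 2*phat, scale sqrt(2*phat*(1-phat)),
# missing entries imputed to the mean (0 after centering); monomorphic
# columns dropped
standardize_genotypes <- function(matrix) {
  g <- matrix$calls
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!all(poly))
    message(sum(!poly), " monomorphic site(s) dropped before PCA")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(g, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  z
}

#' Principal component analysis of genotypes
#'
#' Dosages are standardized per site by the sample allele frequency
#' (center `2*phat`, scale `sqrt(2*phat*(1-phat))`), missing entries
#' mean-imputed, and scores taken from the eigendecomposition of the sample
#' covariance of standardized genotypes.
#'
#' @param matrix an LD-pruned [genotype_matrix()].
#' @param n_components components to retain (default 20, capped at
#'   `n_samples - 1`).
#' @return `list(scores (samples x components), explained (fraction of
#'   variance per component))` of class `pca_result`.
#' @export
pca_genotypes <- function(matrix, n_components = 20) {
  if (length(matrix$samples) < 2) stop("PCA needs at least two samples")
  z <- standardize_genotypes(matrix)
  n <- nrow(z)
  k <- min(n_components, n - 1L)
  cv <- tcrossprod(z) / ncol(z)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  dimnames(scores) <- list(matrix$samples, paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 explained = ev[seq_len(k)] / sum(ev)),
            class = "pca_result")
}

# binomial admixture log-likelihood; G has NAs, P = Q F clamped
admix_loglik <- function(G, Q, F) {
  P <- Q %*% F
  P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
  ll <- G * log(P) + (2 - G) * log(1 - P)
  sum(ll, na.rm = TRUE)
}

em_admixture <- function(G, K, max_iter, tol, init_seed, eps = 1e-6) {
  n <- nrow(G); m <- ncol(G)
  set.seed(init_seed)
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  F <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
  Gz <- G; Gz[is.na(G)] <- 0L           # missing entries contribute nothing
  storage.mode(Gz) <- "double"
  G2z <- 2 - G; G2z[is.na(G)] <- 0L
  storage.mode(G2z) <- "double"
  mi <- rowSums(!is.na(G))
  ll_trace <- numeric(max_iter)
  it <- 0L
  repeat {
    it <- it + 1L
    P <- Q %*% F
    P[P < 1e-9] <- 1e-9; P[P > 1 - 1e-9] <- 1 - 1e-9
    A <- Gz / P                          # n x m
    B <- G2z / (1 - P)
    ll_trace[it] <- sum(Gz * log(P)) + sum(G2z * log1p(-P))
    if ((it > 1 && ll_trace[it] - ll_trace[it - 1] < tol) || it >= max_iter)
      break
    # F update: f <- f * t(Q)A / (f * t(Q)A + (1-f) * t(Q)B)
    TA <- crossprod(Q, A)                # K x m
    TB <- crossprod(Q, B)
    Fnew <- F * TA / (F * TA + (1 - F) * TB)
    # Q update uses the same responsibilities (old F)
    Qnew <- Q * (A %*% t(F) + B %*% t(1 - F)) / (2 * mi)
    Q <- Qnew / rowSums(Qnew)
    Fnew[Fnew < eps] <- eps; Fnew[Fnew > 1 - eps] <- 1 - eps
    F <- Fnew
  }
  ll_trace <- ll_trace[seq_len(it)]
  list(Q = Q, F = F, loglik = admix_loglik(G, Q, F),
       n_iterations = it, loglik_trace = ll_trace)
}

#' Fit a K-cluster admixture model by EM
#'
#' Maximizes the binomial genotype likelihood
#' `sum_ij [ g_ij log(QF)_ij + (2 - g_ij) log(1 - (QF)_ij) ]` (missing
#' genotypes skipped) over ancestry fractions Q (rows sum to 1) and cluster
#' allele frequencies F (clamped to `[1e-6, 1 - 1e-6]`), by multiplicative
#' EM updates from random initialization. The best of `n_restarts` runs (by
#' log-likelihood) is returned. `K = 1` has the closed-form solution Q = 1,
#' F = sample allele frequencies, which EM reaches in one step.
#'
#' @param matrix an LD-pruned [genotype_matrix()].
#' @param K number of ancestral clusters.
#' @param max_iter maximum EM iterations (default 2000).
#' @param tol stop when the log-likelihood gain falls below this (default
#'   1e-4).
#' @param seed integer seed (restart seeds derive from it).
#' @param n_restarts random restarts (default 5).
#' @return `list(K, Q, F, loglik, n_iterations, loglik_trace, seed)` of class
#'   `ancestry_fit`. Q rows are named by sample.
#' @export
fit_admixture <- function(matrix, K, max_iter = 2000, tol = 1e-4, seed = 1,
                          n_restarts = 5) {
  if (K < 1) stop("K must be >= 1")
  if (K > length(matrix$samples)) stop("K exceeds the number of samples")
  G <- matrix$calls
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max, n_restarts)
  best <- NULL
  for (s in restart_seeds) {
    fit <- em_admixture(G, K, max_iter, tol, s)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  rownames(best$Q) <- matrix$samples
  structure(c(list(K = K, seed = seed), best), class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("ancestry_fit: K =", x$K, " loglik =", format(x$loglik),
      " (", x$n_iterations, "EM iterations )\n")
  invisible(x)
}

#' Cross-validation error of an admixture fit
#'
#' Genotype *entries* (sample x site cells) are partitioned at random into
#' `n_folds` folds. Each fold is masked in turn, the model refitted on the
#' remainder, and the masked entries predicted as dosage `2 * (QF)_ij`; the
#' error is the mean binomial deviance over masked entries. This mirrors the
#' masking cross-validation used to pick K in model-based ancestry software.
#'
#' @param matrix an LD-pruned [genotype_matrix()].
#' @param K number of clusters.
#' @param n_folds folds (default 5).
#' @param seed integer seed (controls folds and refit initialization).
#' @param max_iter,tol,n_restarts EM controls for the per-fold refits.
#' @return Scalar CV error.
#' @export
cv_error <- function(matrix, K, n_folds = 5, seed = 1, max_iter = 2000,
                     tol = 1e-4, n_restarts = 2) {
  G <- matrix$calls
  obs <- which(!is.na(G))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), length(obs)))
  fold_seeds <- sample.int(.Machine$integer.max, n_folds)
  dev <- 0; n_pred <- 0L
  for (f in seq_len(n_folds)) {
    masked <- obs[fold == f]
    Gtrain <- G
    Gtrain[masked] <- NA_integer_
    train <- matrix
    train$calls <- Gtrain
    fit <- fit_admixture(train, K, max_iter = max_iter, tol = tol,
                         seed = fold_seeds[f], n_restarts = n_restarts)
    P <- fit$Q %*% fit$F
    P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
    g <- G[masked]; p <- P[masked]
    # sites unobserved in a fold's training data carry no information
    seen <- colSums(!is.na(Gtrain)) > 0
    keep <- seen[((masked - 1L) %/% nrow(G)) + 1L]
    g <- g[keep]; p <- p[keep]
    dev <- dev - 2 * sum(g * log(p) + (2 - g) * log(1 - p))
    n_pred <- n_pred + length(g)
  }
  dev / n_pred
}

#' Cross-validation curve over a range of K
#'
#' @param matrix an LD-pruned [genotype_matrix()].
#' @param K_range integer vector of K values (default 1:6).
#' @param n_folds folds per K.
#' @param seed integer seed shared across K so folds are common.
#' @param ... passed to [cv_error()].
#' @return `list(curve = data.frame(K, cv_error), optimal_K)`.
#' @export
cv_curve <- function(matrix, K_range = 1:6, n_folds = 5, seed = 1, ...) {
  err <- vapply(K_range, function(k)
    cv_error(matrix, k, n_folds = n_folds, seed = seed, ...), numeric(1))
  curve <- data.frame(K = K_range, cv_error = err)
  list(curve = curve, optimal_K = K_range[which.min(err)])
}

#' Align the columns of one Q matrix onto another
#'
#' Cluster labels are arbitrary; to compare fits the columns of `Q` are
#' greedily matched to the columns of `reference` by maximal correlation.
#'
#' @param Q,reference n x K ancestry matrices.
#' @return `Q` with columns permuted to best match `reference`.
#' @export
align_q <- function(Q, reference) {
  K <- ncol(Q)
  stopifnot(ncol(reference) == K)
  cc <- suppressWarnings(stats::cor(reference, Q))
  cc[is.na(cc)] <- 0
  perm <- integer(K)
  used <- logical(K)
  for (step in seq_len(K)) {
    cand <- which(cc == max(cc[!is.na(cc)]), arr.ind = TRUE)[1, ]
    perm[cand[1]] <- cand[2]
    cc[cand[1], ] <- -Inf
    cc[, cand[2]] <- -Inf
  }
  Q[, perm, drop = FALSE]
}
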