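#' Principal-component neural modes of binned activity
#'
#' Centers the bins x neurons count matrix per neuron (no variance
#' scaling: counts share units) and returns the top-D right singular
#' vectors plus the full variance-explained spectrum.
#'
#' @param rates a `binned_rates` matrix (neurons x bins), or any numeric
#'   neurons x bins matrix
#' @param d number of modes to keep
#' @return a `mode_matrix`: N x D orthonormal matrix with attribute
#'   `variance_explained` (full spectrum, fractions summing to 1)
#' @export
pca_modes <- function(rates, d) {
  X <- t(unclass(rates))                    # bins x neurons
  stopifnot(nrow(X) >= d + 1)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  ve <- sv$d^2 / sum(sv$d^2)
  structure(sv$v[, seq_len(d), drop = FALSE],
            variance_explained = ve,
            class = c("mode_matrix", "matrix", "array"))
}

#' Factor-analysis neural modes
#'
#' Maximum-likelihood factor analysis with D factors and per-neuron
#' (diagonal) noise, fitted by EM on the sample covariance — the
#' appropriate route when neurons far outnumber bins. Returns the N x D
#' loading matrix.
#'
#' @inheritParams pca_modes
#' @param tol convergence tolerance on the log-likelihood change
#' @param max_iter maximum EM iterations
#' @return a `mode_matrix` (loadings; columns not orthonormal) with
#'   attributes `loglik` and `iterations`
#' @export
fa_modes <- function(rates, d, tol = 1e-3, max_iter = 1000) {
  X <- t(unclass(rates))
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= d + 1)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n
  vars <- diag(S)
  floorv <- 1e-8 * mean(vars) + 1e-12
  # init from PCA
  sv <- svd(Xc, nu = 0, nv = d)
  ev <- (sv$d[seq_len(d)]^2) / n
  L <- sv$v %*% diag(sqrt(pmax(ev, floorv)), d)
  Psi <- pmax(vars - rowSums(L^2), floorv)
  ll_old <- -Inf
  iter <- 0
  ll <- ll_old
  repeat {
    iter <- iter + 1
    PsiL <- L / Psi                          # p x d  (Psi^-1 L)
    G <- diag(d) + crossprod(L, PsiL)        # I + L' Psi^-1 L
    Gi <- solve(G)
    beta <- Gi %*% t(PsiL)                   # d x p  (= L' Sigma^-1)
    bS <- beta %*% S                         # d x p
    M <- diag(d) - beta %*% L + bS %*% t(beta)  # E[zz']
    L_new <- t(bS) %*% solve(M)
    Psi <- pmax(diag(S) - rowSums(L_new * t(bS)), floorv)
    L <- L_new
    # log-likelihood via Woodbury
    PsiL <- L / Psi
    G <- diag(d) + crossprod(L, PsiL)
    logdet <- 2 * sum(log(diag(chol(G)))) + sum(log(Psi))
    # tr(Sigma^-1 S) via Woodbury: tr(Psi^-1 S) - tr(G^-1 (PsiL)' S PsiL)
    trSiS <- sum(diag(S) / Psi) - sum(t(PsiL) * (solve(G, t(PsiL) %*% S)))
    ll <- -n / 2 * (p * log(2 * pi) + logdet + trSiS)
    if (abs(ll - ll_old) < tol || iter >= max_iter) break
    ll_old <- ll
  }
  if (iter >= max_iter && abs(ll - ll_old) >= tol)
    stop("factor analysis did not converge in ", iter, " iterations")
  structure(L, loglik = ll, iterations = iter,
            class = c("mode_matrix", "matrix", "array"))
}

#' Cosine of the mean principal angle between two subspaces
#'
#' Orthonormalizes both bases; the cosines of the principal angles are the
#' singular values of the cross-product of the orthonormal bases (clipped
#' to \[0, 1\] before `acos` for numerical safety). Returns
#' `cos(mean(angles))`: 1 for identical subspaces, 0 for orthogonal ones.
#' The value is invariant to any invertible recombination of either basis.
#'
#' @param A,B matrices whose columns span the subspaces
#' @return a number in \[0, 1\]
#' @export
subspace_cosine <- function(A, B) {
  qa <- qr(as.matrix(A)); qb <- qr(as.matrix(B))
  if (qa$rank < ncol(as.matrix(A)) || qb$rank < ncol(as.matrix(B)))
    stop("rank-deficient input basis")
  Qa <- qr.Q(qa); Qb <- qr.Q(qb)
  s <- svd(crossprod(Qa, Qb))$d
  s <- pmin(pmax(s, 0), 1)
  cos(mean(acos(s)))
}

#' Mean absolute column-wise correlation
#'
#' `mean_i |corr(A[, i], B[, i])|` — unlike [subspace_cosine()], this
#' detects within-manifold permutations (a column swap of orthogonal
#' random columns drops it to ~0 while the subspace cosine stays 1).
#'
#' @param A,B matrices of matched shape (N x D)
#' @return a number in \[0, 1\]
#' @export
columnwise_similarity <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  sds <- apply(A, 2, stats::sd) * apply(B, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance column")
  mean(abs(diag(stats::cor(A, B))))
}

#' Element-wise similarity of two weight matrices
#'
#' Pearson correlation over all flattened entries plus the Frobenius norm
#' of the difference. The correlation is blind to global additive or
#' multiplicative rescaling; the Frobenius norm is not.
#'
#' @param w_old,w_new matched N x N matrices
#' @return a one-row tibble: `pearson`, `frobenius`
#' @export
weight_similarity <- function(w_old, w_new) {
  stopifnot(all(dim(w_old) == dim(w_new)))
  tibble::tibble(
    pearson = stats::cor(as.numeric(w_old), as.numeric(w_new)),
    frobenius = sqrt(sum((w_old - w_new)^2)))
}

#' Pairwise subspace similarities among named bases
#'
#' Computes [subspace_cosine()] for every pair of the supplied matrices —
#' the generalized-correlation matrix relating encoders, decoders and
#' empirical neural modes.
#'
#' @param ... named matrices (e.g. `K = K, Phi_T = t(Phi), Z_PCA = z)`)
#' @return a tibble with columns `a`, `b`, `cosine`
#' @export
subspace_similarity_table <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 2, !is.null(names(mats)))
  nm <- names(mats)
  pairs <- utils::combn(length(mats), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble::tibble(a = nm[a], b = nm[b],
                   cosine = subspace_cosine(mats[[a]], mats[[b]]))
  })
}
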