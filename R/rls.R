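# Laplacian regularized least squares smoothing. The normalized Laplacians
# of the two similarity networks define smoothing kernels
# K = S (S + eta L S)^{-1}, the closed-form minimizers of a Laplacian
# regularized least-squares objective; applied to the walk scores they
# down-weight jumps through promiscuously similar nodes.

#' Symmetric normalized graph Laplacian of a similarity matrix
#'
#' `L = M^{-1/2} (M - S) M^{-1/2}` with `M = diag(row sums of S)`.
#' Symmetric positive semidefinite; zero for the identity similarity.
#'
#' @param S Similarity matrix (unit diagonal guarantees positive row sums).
#' @return Named symmetric matrix of the same dimension.
#' @export
normalized_laplacian <- function(S) {
  rs <- rowSums(S)
  if (any(rs <= 0)) stop("similarity matrix has a nonpositive row sum")
  d <- 1 / sqrt(rs)
  L <- -(d * S) * rep(d, each = nrow(S))   # M^{-1/2} S M^{-1/2}, negated
  diag(L) <- diag(L) + 1                   # M^{-1/2} M M^{-1/2} = I
  dimnames(L) <- dimnames(S)
  (L + t(L)) / 2
}

#' Regularized least-squares smoothing kernel
#'
#' `K = S (S + eta L S)^{-1}`, computed via a linear solve (never an
#' explicit inverse) and validated by the residual
#' `||K (S + eta L S) - S||_F <= 1e-8 ||S||_F`. With `eta = 0` and
#' invertible `S` the kernel is the identity. A singular system is retried
#' once with a small ridge `1e-10 * trace(S) / n` on the diagonal (with a
#' warning); if that also fails, an error suggests increasing the ridge.
#'
#' @param S Similarity matrix.
#' @param L Its normalized Laplacian ([normalized_laplacian()]).
#' @param eta Trade-off parameter (>= 0).
#' @return Named square matrix (the kernel).
#' @export
rls_kernel <- function(S, L, eta) {
  stopifnot(eta >= 0, identical(dim(S), dim(L)))
  B <- S + eta * (L %*% S)
  solve_right <- function(B) t(solve(t(B), t(S)))  # K B = S  =>  B' K' = S'
  K <- tryCatch(solve_right(B), error = function(e) {
    ridge <- 1e-10 * sum(diag(S)) / nrow(S)
    warning("singular RLS system; retrying with ridge ", format(ridge),
            call. = FALSE)
    tryCatch(solve_right(B + ridge * diag(nrow(B))),
             error = function(e2)
               stop("RLS system singular even with ridge ", format(ridge),
                    "; increase the ridge or check the similarity matrix",
                    call. = FALSE))
  })
  res <- norm(K %*% B - S, "F")
  if (res > 1e-8 * max(norm(S, "F"), .Machine$double.eps))
    stop("RLS kernel residual too large: ", format(res))
  dimnames(K) <- dimnames(S)
  K
}

#' Kernel-smooth walk scores
#'
#' Cross-space smoothing (the default pairing): the lncRNA-walk scores are
#' smoothed along the disease axis, `P_l <- P_l %*% t(K_d)`, and the
#' disease-walk scores along the lncRNA axis, `P_d <- K_l %*% P_d`. With
#' `cross_pairing = FALSE` each walk is instead smoothed in its own space
#' (`K_l %*% P_l`, `P_d %*% t(K_d)`), for sensitivity analysis.
#'
#' @param P_l,P_d Walk score matrices (lncRNAs x diseases).
#' @param K_l,K_d Smoothing kernels from [rls_kernel()] for the lncRNA and
#'   disease networks.
#' @param cross_pairing Logical; see above.
#' @return List with smoothed `P_l` and `P_d`.
#' @export
smooth_scores <- function(P_l, P_d, K_l, K_d, cross_pairing = TRUE) {
  stopifnot(identical(dim(P_l), dim(P_d)),
            nrow(K_l) == nrow(P_l), nrow(K_d) == ncol(P_l))
  if (cross_pairing) {
    list(P_l = P_l %*% t(K_d), P_d = K_l %*% P_d)
  } else {
    list(P_l = K_l %*% P_l, P_d = P_d %*% t(K_d))
  }
}

#' Fuse the two walk scores
#'
#' Entrywise mean of the lncRNA-network and disease-network scores.
#'
#' @param P_l,P_d Score matrices of identical shape.
#' @return Score matrix `(P_l + P_d) / 2`.
#' @export
fuse <- function(P_l, P_d) {
  stopifnot(identical(dim(P_l), dim(P_d)))
  (P_l + P_d) / 2
}

#' Predict association scores
#'
#' End-to-end composition: normalized Laplacians and RLS kernels are built
#' from the two similarity matrices; the unbalanced bi-random walk is run
#' with `n_l` steps on the lncRNA network and `n_d` on the disease network;
#' kernel smoothing is applied after every step (`smoothing_mode =
#' "per_step"`) or once at the end (`"final"`); the two score matrices are
#' averaged. Deterministic given inputs and parameters.
#'
#' @param Y Binary association matrix (lncRNAs x diseases).
#' @param Sl,Sd lncRNA and disease similarity matrices matching the axes
#'   of `Y`.
#' @param params [model_params()].
#' @return Score matrix of association probabilities (lncRNAs x diseases).
#' @export
predict_associations <- function(Y, Sl, Sd, params = model_params()) {
  stopifnot(nrow(Sl) == nrow(Y), nrow(Sd) == ncol(Y))
  K_l <- rls_kernel(Sl, normalized_laplacian(Sl), params$eta_l)
  K_d <- rls_kernel(Sd, normalized_laplacian(Sd), params$eta_d)
  smooth_l <- function(P) {
    if (params$cross_pairing) P %*% t(K_d) else K_l %*% P
  }
  smooth_d <- function(P) {
    if (params$cross_pairing) K_l %*% P else P %*% t(K_d)
  }
  if (params$smoothing_mode == "per_step") {
    P_l <- walk_iterate(Y, Sl, params$gamma, params$n_l, side = "lncrna",
                        after_step = smooth_l)
    P_d <- walk_iterate(Y, Sd, params$gamma, params$n_d, side = "disease",
                        after_step = smooth_d)
  } else {
    P_l <- smooth_l(lncrna_walk(Y, Sl, params$gamma, params$n_l))
    P_d <- smooth_d(disease_walk(Y, Sd, params$gamma, params$n_d))
  }
  P <- fuse(P_l, P_d)
  dimnames(P) <- dimnames(Y)
  P
}
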