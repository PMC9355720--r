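# Unbalanced bi-random walk: association evidence is propagated over the
# lncRNA and disease similarity networks with independent step counts.
# Similarity matrices enter exactly as given (no row-stochastic
# normalization); downstream ranking is invariant to the resulting scale.

walk_iterate <- function(Y, S, gamma, n, side = c("lncrna", "disease"),
                         after_step = NULL) {
  side <- match.arg(side)
  stopifnot(gamma >= 0, gamma < 1, n >= 0)
  if (side == "lncrna" && !identical(dim(S), c(nrow(Y), nrow(Y))))
    stop("lncRNA similarity does not match the lncRNA axis of Y")
  if (side == "disease" && !identical(dim(S), c(ncol(Y), ncol(Y))))
    stop("disease similarity does not match the disease axis of Y")
  P <- Y
  for (t in seq_len(n)) {
    P <- if (side == "lncrna") gamma * (S %*% P) + (1 - gamma) * Y
         else                  gamma * (P %*% S) + (1 - gamma) * Y
    if (!is.null(after_step)) P <- after_step(P)
  }
  dimnames(P) <- dimnames(Y)
  P
}

#' Random walk on the lncRNA similarity network
#'
#' Starting from the association matrix `P0 = Y`, iterates
#' `P_t = gamma * Sl %*% P_{t-1} + (1 - gamma) * Y` for `n_l` steps and
#' returns the final scores. With `n_l = 0` the result is `Y` exactly.
#'
#' @param Y Association matrix (lncRNAs x diseases); real-valued scores are
#'   allowed (the walk is linear in `Y`).
#' @param Sl lncRNA similarity matrix.
#' @param gamma Restart weight in (0, 1).
#' @param n_l Step count (integer >= 0).
#' @return Score matrix with the axes of `Y`.
#' @export
lncrna_walk <- function(Y, Sl, gamma, n_l) {
  walk_iterate(Y, Sl, gamma, n_l, side = "lncrna")
}

#' Random walk on the disease similarity network
#'
#' Mirror of [lncrna_walk()] on the disease axis:
#' `P_t = gamma * P_{t-1} %*% Sd + (1 - gamma) * Y` for `n_d` steps.
#'
#' @param Y Association matrix (lncRNAs x diseases).
#' @param Sd Disease similarity matrix.
#' @param gamma Restart weight in (0, 1).
#' @param n_d Step count (integer >= 0).
#' @return Score matrix with the axes of `Y`.
#' @export
disease_walk <- function(Y, Sd, gamma, n_d) {
  walk_iterate(Y, Sd, gamma, n_d, side = "disease")
}

#' Fixed point of the walk recursion
#'
#' The limit of the walk iteration as the step count grows, valid when
#' `gamma * spectral_radius(S) < 1`:
#' `(1 - gamma) * (I - gamma S)^{-1} Y` on the lncRNA side (the disease
#' side multiplies on the right). Serves as a convergence oracle.
#'
#' @inheritParams lncrna_walk
#' @param S Similarity matrix for the chosen side.
#' @param side `"lncrna"` (left multiplication) or `"disease"` (right).
#' @return Score matrix with the axes of `Y`.
#' @export
walk_fixed_point <- function(Y, S, gamma, side = c("lncrna", "disease")) {
  side <- match.arg(side)
  rho <- max(Mod(eigen(S, only.values = TRUE)$values))
  if (gamma * rho >= 1)
    stop("fixed point undefined: gamma * spectral_radius(S) >= 1")
  A <- diag(nrow(S)) - gamma * S
  P <- if (side == "lncrna") (1 - gamma) * solve(A, Y)
       else                  (1 - gamma) * t(solve(t(A), t(Y)))
  dimnames(P) <- dimnames(Y)
  P
}
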