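#' Model parameters for association prediction
#'
#' Bundles every tunable of the prediction pipeline. Defaults are the
#' published operating point of the method: semantic decay `alpha = 0.5`,
#' walk restart weight `gamma = 0.001`, 31 propagation steps on the lncRNA
#' network and 1 on the disease network, and regularized least-squares
#' trade-offs `eta_l = eta_d = 0.01`.
#'
#' @param alpha Semantic decay per ontology edge, in (0, 1). Each step away
#'   from the disease term multiplies its contribution by `alpha` (plus the
#'   information-content correction under the `"SV3"` variant).
#' @param gamma Restart weight of the random walk, in (0, 1). Small values
#'   keep the propagated scores close to the known association matrix.
#' @param n_l Number of walk steps on the lncRNA similarity network
#'   (integer >= 0).
#' @param n_d Number of walk steps on the disease similarity network
#'   (integer >= 0).
#' @param eta_l,eta_d Laplacian regularization trade-offs (>= 0) for the
#'   lncRNA and disease smoothing kernels.
#' @param contribution_variant Disease semantic-contribution variant:
#'   `"SV1"` (pure decay), `"SV2"` (information content only) or `"SV3"`
#'   (decay plus information-content correction; the default).
#' @param smoothing_mode `"per_step"` applies the kernel smoothing after
#'   every walk iteration; `"final"` applies it once after the last step.
#' @param cross_pairing If `TRUE` (default) the disease-space kernel smooths
#'   the lncRNA-walk scores and vice versa; `FALSE` switches to same-space
#'   pairing for sensitivity analysis.
#' @param beta_at_child If `TRUE`, the information-content factor in the
#'   `"SV3"` recursion is evaluated at the child term instead of the term
#'   being scored. Off by default.
#'
#' @return An object of class `birwrls_params` (a named list).
#' @examples
#' p <- model_params()
#' p$gamma
#' @export
model_params <- function(alpha = 0.5, gamma = 0.001, n_l = 31L, n_d = 1L,
                         eta_l = 0.01, eta_d = 0.01,
                         contribution_variant = c("SV3", "SV1", "SV2"),
                         smoothing_mode = c("per_step", "final"),
                         cross_pairing = TRUE, beta_at_child = FALSE) {
  contribution_variant <- match.arg(contribution_variant)
  smoothing_mode <- match.arg(smoothing_mode)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
    is.numeric(gamma), length(gamma) == 1L, gamma > 0, gamma < 1,
    is.numeric(n_l), length(n_l) == 1L, n_l >= 0, n_l == round(n_l),
    is.numeric(n_d), length(n_d) == 1L, n_d >= 0, n_d == round(n_d),
    is.numeric(eta_l), eta_l >= 0, is.numeric(eta_d), eta_d >= 0,
    is.logical(cross_pairing), is.logical(beta_at_child)
  )
  structure(list(
    alpha = alpha, gamma = gamma, n_l = as.integer(n_l), n_d = as.integer(n_d),
    eta_l = eta_l, eta_d = eta_d,
    contribution_variant = contribution_variant,
    smoothing_mode = smoothing_mode,
    cross_pairing = cross_pairing, beta_at_child = beta_at_child
  ), class = "birwrls_params")
}

#' @export
print.birwrls_params <- function(x, ...) {
  cat("birwrls model parameters\n")
  cat(sprintf("  alpha = %g, gamma = %g, n_l = %d, n_d = %d\n",
              x$alpha, x$gamma, x$n_l, x$n_d))
  cat(sprintf("  eta_l = %g, eta_d = %g\n", x$eta_l, x$eta_d))
  cat(sprintf("  variant = %s, smoothing = %s, cross_pairing = %s\n",
              x$contribution_variant, x$smoothing_mode, x$cross_pairing))
  invisible(x)
}
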