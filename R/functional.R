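# lncRNA functional similarity by best-match averaging: two lncRNAs are
# similar when their associated disease sets are semantically close.

#' Disease groups of the lncRNAs
#'
#' @param Y Binary association matrix (lncRNAs x diseases).
#' @return Named list: lncRNA -> character vector of associated diseases
#'   (possibly empty).
#' @export
disease_groups <- function(Y) {
  lapply(stats::setNames(rownames(Y), rownames(Y)),
         function(u) colnames(Y)[Y[u, ] != 0])
}

#' Best match of a disease against a disease group
#'
#' `max over members d' of Sd(d, d')`; 0 for an empty group (an lncRNA can
#' lose all its associations under cross-validation masking).
#'
#' @param d Disease name.
#' @param group Character vector of disease names.
#' @param Sd Disease similarity matrix.
#' @return Real in \[0, 1\].
#' @export
best_match <- function(d, group, Sd) {
  if (length(group) == 0L) return(0)
  max(Sd[d, group])
}

#' Directional group similarity
#'
#' Sum over the first group's diseases of their best match in the second
#' group.
#'
#' @param group_u,group_v Character vectors of disease names.
#' @param Sd Disease similarity matrix.
#' @return Nonnegative real (at most `length(group_u)`).
#' @export
directional_sum <- function(group_u, group_v, Sd) {
  if (length(group_u) == 0L || length(group_v) == 0L) return(0)
  sum(apply(Sd[group_u, group_v, drop = FALSE], 1, max))
}

#' Functional similarity between two lncRNAs
#'
#' Best-match average over the two associated disease sets:
#' `(S_{u->v} + S_{v->u}) / (|DG(u)| + |DG(v)|)`. Symmetric, in \[0, 1\];
#' equals 1 for identical nonempty groups. Two isolated lncRNAs (both
#' groups empty) get 0.
#'
#' @param group_u,group_v The lncRNAs' disease groups.
#' @param Sd Disease similarity matrix.
#' @return Real in \[0, 1\].
#' @export
functional_similarity <- function(group_u, group_v, Sd) {
  nu <- length(group_u); nv <- length(group_v)
  if (nu + nv == 0L) return(0)
  (directional_sum(group_u, group_v, Sd) +
     directional_sum(group_v, group_u, Sd)) / (nu + nv)
}

#' lncRNA functional similarity matrix
#'
#' Pairwise [functional_similarity()] over all lncRNAs of the association
#' matrix; the diagonal is forced to 1 (also for lncRNAs with no remaining
#' associations, whose off-diagonal row is 0).
#'
#' @param Y Binary association matrix (lncRNAs x diseases). Inside
#'   cross-validation this must be the training (masked) matrix so that
#'   held-out positives never leak into the similarity.
#' @param Sd Disease similarity matrix over `colnames(Y)`.
#' @return Symmetric named similarity matrix over the lncRNAs.
#' @export
lncrna_similarity_matrix <- function(Y, Sd) {
  stopifnot(all(colnames(Y) %in% rownames(Sd)))
  groups <- disease_groups(Y)
  lnc <- rownames(Y)
  n <- length(lnc)
  if (any(vapply(groups, length, integer(1)) == 0L))
    message("lncRNA(s) with empty disease group: similarity row set to 0")
  S <- matrix(0, n, n, dimnames = list(lnc, lnc))
  for (i in seq_len(n)) {
    gi <- groups[[i]]
    if (length(gi) == 0L) next
    for (j in seq_len(i - 1L)) {
      S[i, j] <- S[j, i] <- functional_similarity(gi, groups[[j]], Sd)
    }
  }
  diag(S) <- 1
  S
}
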