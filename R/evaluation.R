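# Cross-validated evaluation. Known positives are split into folds;
# each fold is masked from the training matrix (and from the lncRNA
# similarity, which is recomputed per fold to avoid leakage), predictions
# are made, and held-out positives are scored against all unknown pairs.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted half. Computed from midranks, so it
#' agrees exactly with brute-force pair counting.
#'
#' @param pos,neg Numeric score vectors for positives and negatives.
#' @return Real in \[0, 1\].
#' @export
auc_score <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (np == 0L || nn == 0L) stop("need at least one positive and one negative")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Assign known positives to cross-validation folds
#'
#' Uniformly random partition of the positive pairs into `n_folds` folds of
#' sizes differing by at most 1; deterministic given the seed.
#'
#' @param Y Binary association matrix.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer RNG seed.
#' @return A list of class `cv_plan`: `pairs` (two-column index matrix of
#'   the positives), `fold` (integer fold label per positive), `n_folds`,
#'   `seed`.
#' @export
make_folds <- function(Y, n_folds = 5L, seed = 42L) {
  pairs <- which(Y != 0, arr.ind = TRUE)
  if (nrow(pairs) < n_folds)
    stop("fewer positives (", nrow(pairs), ") than folds (", n_folds, ")")
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  fold <- withr::with_seed(seed,
    sample(rep(seq_len(n_folds), length.out = nrow(pairs))))
  structure(list(pairs = pairs, fold = fold,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Cross-validate the association predictor
#'
#' For each fold: the fold's positives are masked to 0 in the training
#' matrix; the lncRNA similarity is recomputed from the masked matrix
#' (disease similarity comes from the ontology and does not depend on Y);
#' scores are predicted; the AUC of the held-out positives against all
#' pairs that are 0 in the full matrix is computed.
#'
#' @param Y Binary association matrix (lncRNAs x diseases).
#' @param Sd Disease similarity matrix.
#' @param params [model_params()].
#' @param plan A [make_folds()] plan built from the same `Y`.
#' @param leak_similarity If `TRUE`, the lncRNA similarity is (wrongly)
#'   computed from the full matrix including held-out positives — a switch
#'   kept to demonstrate how leakage inflates the AUC. Default `FALSE`.
#' @return A list of class `cv_result`: `per_fold_auc`, `mean_auc`,
#'   `pooled_auc` (positives pooled over folds against the common negative
#'   set), `n_test_pos` and `n_neg` per fold, `seed`.
#' @export
cross_validate <- function(Y, Sd, params = model_params(),
                           plan = make_folds(Y), leak_similarity = FALSE) {
  stopifnot(inherits(plan, "cv_plan"))
  neg_idx <- which(Y == 0)
  per_fold <- numeric(plan$n_folds)
  n_test <- integer(plan$n_folds)
  pooled_pos <- vector("list", plan$n_folds)
  pooled_neg <- vector("list", plan$n_folds)
  Sl_full <- if (leak_similarity) lncrna_similarity_matrix(Y, Sd) else NULL
  for (f in seq_len(plan$n_folds)) {
    test <- plan$pairs[plan$fold == f, , drop = FALSE]
    if (nrow(test) == 0L) stop("fold ", f, " has no test positives")
    Ytrain <- Y
    Ytrain[test] <- 0L
    Sl <- if (leak_similarity) Sl_full
          else suppressMessages(lncrna_similarity_matrix(Ytrain, Sd))
    P <- predict_associations(Ytrain, Sl, Sd, params)
    per_fold[f] <- auc_score(P[test], P[neg_idx])
    n_test[f] <- nrow(test)
    pooled_pos[[f]] <- P[test]
    pooled_neg[[f]] <- P[neg_idx]
  }
  structure(list(per_fold_auc = per_fold,
                 mean_auc = mean(per_fold),
                 pooled_auc = auc_score(unlist(pooled_pos),
                                        unlist(pooled_neg)),
                 n_test_pos = n_test,
                 n_neg = length(neg_idx),
                 seed = plan$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cross-validation (seed", x$seed, ")\n")
  cat("  per-fold AUC:", paste(sprintf("%.4f", x$per_fold_auc),
                               collapse = " "), "\n")
  cat(sprintf("  mean AUC: %.4f\n", x$mean_auc))
  invisible(x)
}

#' Top-k candidate report for one disease
#'
#' Ranks lncRNAs by predicted score for the disease and flags which of
#' them are already known associations (the Known/Unconfirmed annotation of
#' candidate-biomarker tables).
#'
#' @param scores Predicted score matrix.
#' @param Y_known Binary matrix of known associations (same axes).
#' @param disease Disease name.
#' @param k Number of candidates (default 30; must not exceed the number
#'   of lncRNAs).
#' @param path Optional TSV output path.
#' @return Data frame `rank`, `lncRNA`, `score`, `known_flag`.
#' @export
top_k_report <- function(scores, Y_known, disease, k = 30L, path = NULL) {
  stopifnot(identical(dim(scores), dim(Y_known)))
  write_rankings(scores, disease, k = k, known = Y_known, path = path)
}
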