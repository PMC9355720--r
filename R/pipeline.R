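#' Run the full prediction pipeline
#'
#' Computes the disease semantic similarity from the ontology records, the
#' lncRNA functional similarity from the association matrix, and the
#' smoothed bi-random-walk association scores.
#'
#' @param records Named list of [disease_record()]s covering `colnames(Y)`.
#' @param Y Binary association matrix (lncRNAs x diseases).
#' @param params [model_params()].
#' @param Sl,Sd Optional precomputed similarity matrices; when supplied
#'   they are validated and used instead of being recomputed.
#' @return List with `scores` (the prediction matrix), `Sl`, `Sd`, and
#'   `params`.
#' @export
run_pipeline <- function(records, Y, params = model_params(),
                         Sl = NULL, Sd = NULL) {
  if (is.null(Sd)) {
    missing <- setdiff(colnames(Y), names(records))
    if (length(missing) > 0L)
      stop("diseases without ontology record: ",
           paste(utils::head(missing, 5), collapse = ", "))
    Sd <- disease_similarity_matrix(records, params)[colnames(Y), colnames(Y)]
  }
  validate_similarity(Sd)
  if (is.null(Sl))
    Sl <- suppressMessages(lncrna_similarity_matrix(Y, Sd))
  validate_similarity(Sl)
  scores <- predict_associations(Y, Sl[rownames(Y), rownames(Y)],
                                 Sd[colnames(Y), colnames(Y)], params)
  list(scores = scores, Sl = Sl, Sd = Sd, params = params)
}
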