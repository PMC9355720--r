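# Disease semantic similarity from hierarchical ontology codes.
#
# Each disease carries one or more MeSH-style tree numbers. Prefix
# truncation of a tree number yields its ancestor codes, so the union of
# prefix closures over a disease's tree numbers is its ancestor DAG. A code
# owned by a dataset disease is identified with that disease (a descriptor
# may sit at several tree positions); unowned codes are anonymous terms.

code_prefixes <- function(code) {
  segs <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(segs), function(i) paste(segs[1:i], collapse = "."),
         character(1))
}

# code -> owning disease key; first owner wins on (unexpected) shared codes
ownership_map <- function(universe) {
  own <- character(0)
  for (key in names(universe)) {
    for (code in universe[[key]]$tree_numbers) {
      if (is.null(own[code]) || is.na(own[code])) own[code] <- key
    }
  }
  own
}

#' Build a disease's ancestor DAG from its tree numbers
#'
#' Nodes are the union, over the record's tree numbers, of all dot-prefix
#' truncations (`"C04.588.894"` yields `C04`, `C04.588`, `C04.588.894`);
#' edges connect each code to its immediate prefix parent. Codes owned by a
#' universe disease collapse to a single node labelled with that disease's
#' (normalized) name — in particular all of the record's own tree numbers
#' collapse to one disease node, which therefore has one parent per tree
#' number. Remaining codes stay as anonymous terms.
#'
#' @param record A [disease_record()].
#' @param universe Named list of all [disease_record()]s in the dataset
#'   (names are normalized disease names), as returned by
#'   [read_disease_table()]. May be `NULL` for a stand-alone DAG.
#' @return A list of class `disease_dag` with fields `disease` (node label
#'   of the record itself), `nodes` (character vector of term labels) and
#'   `children` (named list: term -> child terms).
#' @export
build_dag <- function(record, universe = NULL) {
  stopifnot(inherits(record, "disease_record"))
  self <- normalize_name(record$name)
  own <- if (is.null(universe)) character(0) else ownership_map(universe)
  own[record$tree_numbers] <- self
  label <- function(code) {
    hit <- own[code]
    if (!is.na(hit)) unname(hit) else code
  }
  nodes <- character(0)
  edges <- matrix(character(0), ncol = 2)
  for (tn in record$tree_numbers) {
    codes <- code_prefixes(tn)
    labs <- vapply(codes, label, character(1))
    nodes <- c(nodes, labs)
    if (length(labs) > 1L)
      edges <- rbind(edges, cbind(labs[-length(labs)], labs[-1]))
  }
  nodes <- unique(nodes)
  keep <- edges[, 1] != edges[, 2]
  edges <- unique(edges[keep, , drop = FALSE])
  children <- lapply(stats::setNames(nodes, nodes), function(n)
    unname(edges[edges[, 1] == n, 2]))
  structure(list(disease = self, nodes = nodes, children = children),
            class = "disease_dag")
}

# max over all downward paths of the per-edge factor product; factor(t) is
# applied on the edge leaving t. Memoized sweep; cycle guard errors out.
contribution_sweep <- function(dag, factor_at) {
  memo <- new.env(parent = emptyenv())
  active <- new.env(parent = emptyenv())
  rec <- function(t) {
    if (t == dag$disease) return(1)
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (!is.null(active[[t]])) stop("cycle in disease DAG at term ", t)
    active[[t]] <- TRUE
    kids <- dag$children[[t]]
    if (length(kids) == 0L)
      stop("term ", t, " has no path to disease ", dag$disease)
    val <- max(vapply(kids, function(k) factor_at(t, k) * rec(k), numeric(1)))
    rm(list = t, envir = active)
    memo[[t]] <- val
    val
  }
  stats::setNames(vapply(dag$nodes, rec, numeric(1)), dag$nodes)
}

#' Decay-only semantic contributions (variant SV1)
#'
#' The disease itself contributes 1; every other term contributes the
#' maximum over its children of `alpha` times the child's contribution,
#' i.e. `alpha` to the power of the shortest hop distance to the disease.
#'
#' @param dag A [build_dag()] result.
#' @param alpha Decay per edge, in (0, 1).
#' @return Named numeric vector of contributions (one per DAG term).
#' @export
sv1_contributions <- function(dag, alpha = 0.5) {
  stopifnot(alpha > 0, alpha < 1)
  contribution_sweep(dag, function(t, child) alpha)
}

#' Information-content contribution of a single term (variant SV2)
#'
#' `-log(Dags(t) / D)`: terms shared by many disease DAGs contribute
#' little, rare terms much. Natural logarithm.
#'
#' @param dag_count Number of disease DAGs containing the term (>= 1).
#' @param total_diseases Number of diseases in the corpus.
#' @return Nonnegative real.
#' @export
sv2_contribution <- function(dag_count, total_diseases) {
  stopifnot(total_diseases >= 1)
  if (any(dag_count < 1)) stop("term must occur in at least one DAG")
  -log(dag_count / total_diseases)
}

#' Corpus of disease DAGs with term occurrence statistics
#'
#' Builds every disease's DAG, counts for each term the number of distinct
#' disease DAGs containing it (`Dags(t)`, each disease counted once), and
#' precomputes the information-content factor used by the SV3 variant.
#'
#' @param universe Named list of [disease_record()]s.
#' @return A list of class `dag_corpus` with fields `dags` (named list of
#'   `disease_dag`), `dag_count` (named integer vector over all terms),
#'   `n_diseases`, and `max_count`.
#' @export
dag_corpus <- function(universe) {
  stopifnot(length(universe) > 0)
  dags <- lapply(universe, build_dag, universe = universe)
  counts <- table(unlist(lapply(dags, `[[`, "nodes"), use.names = FALSE))
  dag_count <- stats::setNames(as.integer(counts), names(counts))
  structure(list(dags = dags, dag_count = dag_count,
                 n_diseases = length(universe),
                 max_count = max(dag_count)),
            class = "dag_corpus")
}

#' Information-content correction factor for a term
#'
#' `beta(t) = (max_k Dags(k) - Dags(t)) / D`: 0 for the corpus-wide most
#' frequent term, approaching 1 for terms far rarer than the most frequent
#' one. The maximum ranges over all terms of the corpus.
#'
#' @param term Term label (disease name or anonymous code).
#' @param corpus A [dag_corpus()].
#' @return Value in `[0, 1)`.
#' @export
beta_factor <- function(term, corpus) {
  cnt <- corpus$dag_count[term]
  if (is.na(cnt)) stop("term ", term, " not present in the corpus")
  (corpus$max_count - unname(cnt)) / corpus$n_diseases
}

#' Decay-plus-information-content contributions (variant SV3)
#'
#' Like [sv1_contributions()] but the per-edge factor is `alpha + beta(t)`,
#' where `beta` is the corpus-frequency correction of the term being scored
#' ([beta_factor()]). Contributions are not clamped: with `alpha + beta >= 1`
#' a term may out-contribute its child, as the recursion dictates.
#'
#' @param dag A [build_dag()] result.
#' @param alpha Decay per edge, in (0, 1).
#' @param corpus A [dag_corpus()] containing this disease.
#' @param beta_at_child Evaluate `beta` at the child term instead of the
#'   term being scored (off by default).
#' @return Named numeric vector of contributions.
#' @export
sv3_contributions <- function(dag, alpha = 0.5, corpus, beta_at_child = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  contribution_sweep(dag, function(t, child) {
    alpha + beta_factor(if (beta_at_child) child else t, corpus)
  })
}

#' Semantic value of a disease
#'
#' Sum of the contributions of all terms in the disease's DAG.
#'
#' @param contributions Named contribution vector
#'   ([sv1_contributions()] and friends).
#' @return Nonnegative real (>= 1 for SV1/SV3: the disease contributes 1).
#' @export
semantic_value <- function(contributions) sum(contributions)

#' Semantic similarity between two diseases
#'
#' Shared-ancestor contributions relative to the total semantic values:
#' `sum over shared terms of (SV_A(t) + SV_B(t)) / (SV(A) + SV(B))`.
#' Symmetric, in \[0, 1\], 1 for identical DAGs, 0 for disjoint ones.
#'
#' @param contrib_a,contrib_b Named contribution vectors of the two
#'   diseases, computed with the same variant and parameters.
#' @return Real in \[0, 1\].
#' @export
semantic_similarity <- function(contrib_a, contrib_b) {
  shared <- intersect(names(contrib_a), names(contrib_b))
  denom <- semantic_value(contrib_a) + semantic_value(contrib_b)
  if (denom <= 0) return(0)
  (sum(contrib_a[shared]) + sum(contrib_b[shared])) / denom
}

contributions_for <- function(dag, params, corpus) {
  switch(params$contribution_variant,
    SV1 = sv1_contributions(dag, params$alpha),
    SV2 = stats::setNames(
      sv2_contribution(corpus$dag_count[dag$nodes], corpus$n_diseases),
      dag$nodes),
    SV3 = sv3_contributions(dag, params$alpha, corpus,
                            beta_at_child = params$beta_at_child))
}

#' Disease semantic similarity matrix
#'
#' Applies [semantic_similarity()] to every unordered disease pair under
#' the variant selected in `params`; the diagonal is forced to 1.
#'
#' @param universe Named list of [disease_record()]s (see
#'   [read_disease_table()]).
#' @param params [model_params()].
#' @return Symmetric named similarity matrix over the diseases.
#' @export
disease_similarity_matrix <- function(universe, params = model_params()) {
  corpus <- dag_corpus(universe)
  keys <- names(universe)
  tables <- lapply(keys, function(k)
    contributions_for(corpus$dags[[k]], params, corpus))
  names(tables) <- keys
  n <- length(keys)
  S <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      S[i, j] <- S[j, i] <- semantic_similarity(tables[[i]], tables[[j]])
    }
  }
  diag(S) <- 1
  S
}
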