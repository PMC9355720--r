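# One tabular dialect everywhere: UTF-8, tab-delimited, header row.

#' Normalize a disease or lncRNA name for matching
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space and lowercases. Used as the matching key throughout the
#' package; original spelling is preserved for output.
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names.
#' @export
normalize_name <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  tolower(x)
}

tree_number_ok <- function(code) {
  grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", code)
}

#' Construct a validated disease record
#'
#' @param name Disease label (nonempty string).
#' @param tree_numbers Character vector of dot-separated hierarchical codes
#'   (e.g. `"C04.588.894"`); at least one, each matching the dotted-segment
#'   grammar (nonempty alphanumeric segments, no trailing dot).
#' @return A list of class `disease_record` with fields `name` and
#'   `tree_numbers` (unique, sorted).
#' @export
disease_record <- function(name, tree_numbers) {
  name <- gsub("[[:space:]]+", " ", trimws(as.character(name)))
  if (!nzchar(name)) stop("disease name must be nonempty")
  tree_numbers <- unique(trimws(as.character(tree_numbers)))
  tree_numbers <- tree_numbers[nzchar(tree_numbers)]
  if (length(tree_numbers) == 0L)
    stop("disease '", name, "' has no tree numbers")
  bad <- tree_numbers[!tree_number_ok(tree_numbers)]
  if (length(bad) > 0L)
    stop("malformed tree number(s) for disease '", name, "': ",
         paste(bad, collapse = ", "))
  structure(list(name = name, tree_numbers = sort(tree_numbers)),
            class = "disease_record")
}

#' Read a disease table (name to tree numbers) from TSV
#'
#' Expects columns `disease_name` and `tree_numbers` (semicolon-separated
#' codes). Names are whitespace-normalized; duplicate names (after
#' case-insensitive matching) are merged by unioning their tree numbers.
#' Records with malformed tree numbers are rejected with a warning that
#' names the offending line.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A named list of [disease_record()] objects (names normalized).
#' @export
read_disease_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  if (nrow(tab) == 0L) stop("empty disease table: ", path)
  if (!all(c("disease_name", "tree_numbers") %in% names(tab)))
    stop("disease table must have columns 'disease_name' and 'tree_numbers'")
  records <- list()
  for (i in seq_len(nrow(tab))) {
    rec <- tryCatch(
      disease_record(tab$disease_name[i],
                     strsplit(tab$tree_numbers[i], ";", fixed = TRUE)[[1]]),
      error = function(e) {
        warning("rejecting line ", i + 1L, " of ", basename(path), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(rec)) next
    key <- normalize_name(rec$name)
    if (!is.null(records[[key]])) {
      records[[key]]$tree_numbers <-
        sort(unique(c(records[[key]]$tree_numbers, rec$tree_numbers)))
    } else {
      records[[key]] <- rec
    }
  }
  if (length(records) == 0L) stop("no valid disease records in ", path)
  records
}

#' Read an association pair list into a binary matrix
#'
#' Reads a TSV of `(lncRNA_name, disease_name)` pairs and returns the binary
#' association matrix Y with lncRNAs as rows and diseases as columns (the
#' fixed package-wide orientation). Duplicate pairs collapse to a single 1.
#'
#' @param path Path to a tab-delimited pair file with a header row
#'   (columns `lncRNA_name`, `disease_name`).
#' @param lncrna_names,disease_names Optional explicit name universes.
#'   When supplied, pairs naming an unknown member are an error; when
#'   omitted, the universes are inferred from the file (sorted).
#' @return Binary integer matrix with `dimnames = list(lncRNAs, diseases)`.
#' @export
read_associations <- function(path, lncrna_names = NULL, disease_names = NULL) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  if (!all(c("lncRNA_name", "disease_name") %in% names(tab)))
    stop("association table must have columns 'lncRNA_name' and 'disease_name'")
  lnc <- normalize_name(tab$lncRNA_name)
  dis <- normalize_name(tab$disease_name)
  association_matrix(lnc, dis,
                     lncrna_names = lncrna_names,
                     disease_names = disease_names)
}

#' Build a binary association matrix from name pairs
#'
#' @param lncrnas,diseases Equal-length character vectors of paired names
#'   (one known association per element).
#' @param lncrna_names,disease_names Optional explicit axis universes; when
#'   `NULL` they are the sorted distinct names seen in the pairs.
#' @return Binary integer matrix, lncRNAs x diseases.
#' @export
association_matrix <- function(lncrnas, diseases,
                               lncrna_names = NULL, disease_names = NULL) {
  stopifnot(length(lncrnas) == length(diseases))
  if (is.null(lncrna_names)) lncrna_names <- sort(unique(lncrnas))
  if (is.null(disease_names)) disease_names <- sort(unique(diseases))
  if (anyDuplicated(lncrna_names) || anyDuplicated(disease_names))
    stop("axis names must be unique")
  bad_l <- setdiff(lncrnas, lncrna_names)
  bad_d <- setdiff(diseases, disease_names)
  if (length(bad_l) || length(bad_d))
    stop("pairs name unknown entities: ",
         paste(unique(c(bad_l, bad_d)), collapse = ", "))
  Y <- matrix(0L, length(lncrna_names), length(disease_names),
              dimnames = list(lncrna_names, disease_names))
  if (length(lncrnas) > 0L)
    Y[cbind(match(lncrnas, lncrna_names), match(diseases, disease_names))] <- 1L
  Y
}

#' Validate a similarity matrix
#'
#' Checks that a matrix is square, named, symmetric (to `tol`), has unit
#' diagonal and entries in \[0, 1\].
#'
#' @param S Numeric matrix with identical row and column names.
#' @param tol Symmetry tolerance (default `1e-10`).
#' @return `S`, invisibly, after validation.
#' @export
validate_similarity <- function(S, tol = 1e-10) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S)))
    stop("similarity matrix must carry identical row and column names")
  if (max(abs(S - t(S))) > tol) stop("similarity matrix is not symmetric")
  if (max(abs(diag(S) - 1)) > tol) stop("similarity diagonal must be 1")
  if (min(S) < -tol || max(S) > 1 + tol)
    stop("similarity entries must lie in [0, 1]")
  invisible(S)
}

#' Write / read a named numeric matrix as TSV
#'
#' The first column holds row names (header `name`); remaining columns are
#' named after the matrix columns. Full double precision is retained so that
#' a write/read round trip reproduces values to better than 1e-12.
#'
#' @param M Named numeric matrix.
#' @param path Output/input path.
#' @return `read_matrix_tsv` returns the matrix; `write_matrix_tsv` its
#'   path, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  df <- data.frame(name = rownames(M),
                   format(M, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- df[[1]]
  M
}

#' Export a score matrix as TSV
#'
#' Scores are serialized with 6 significant digits (ranking exports do not
#' need more precision; use [write_matrix_tsv()] for lossless storage).
#'
#' @param scores Named numeric matrix (lncRNAs x diseases).
#' @param path Output path.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(is.matrix(scores), all(is.finite(scores)))
  write_matrix_tsv(signif(scores, 6), path)
}

#' Rank lncRNAs for one disease
#'
#' Sorts lncRNAs by descending score for the named disease; ties are broken
#' by ascending lncRNA name so output is deterministic.
#'
#' @param scores Named score matrix (lncRNAs x diseases).
#' @param disease Disease (column) name.
#' @param k Number of top lncRNAs to return; must not exceed `nrow(scores)`.
#' @param known Optional binary matrix with the same axes; fills the
#'   `known_flag` column (1 = already a known association).
#' @param path Optional TSV output path.
#' @return A data.frame with columns `rank`, `lncRNA`, `score`, `known_flag`.
#' @export
write_rankings <- function(scores, disease, k = nrow(scores), known = NULL,
                           path = NULL) {
  stopifnot(is.matrix(scores))
  if (!disease %in% colnames(scores))
    stop("unknown disease: ", disease)
  if (k > nrow(scores)) stop("k exceeds the number of lncRNAs")
  s <- scores[, disease]
  ord <- order(-s, rownames(scores))[seq_len(k)]
  flag <- if (is.null(known)) rep(NA_integer_, k) else
    as.integer(known[ord, disease] != 0)
  out <- data.frame(rank = seq_len(k),
                    lncRNA = rownames(scores)[ord],
                    score = signif(s[ord], 6),
                    known_flag = flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  out
}
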