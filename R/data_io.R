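# Matrix containers and delimited text I/O.
#
# All matrices are plain numeric matrices with dimnames carrying the
# drug/disease/feature identifiers, plus a class attribute so that validators
# and printers can dispatch. The on-disk dialect is tab-delimited UTF-8 with a
# header row of column identifiers and a first column of row identifiers.

#' Construct a binary drug feature table
#'
#' A features-by-drugs indicator matrix for one evidence type: chemical
#' substructures, target-protein domains, or target-protein annotations.
#'
#' @param values numeric matrix (features x drugs) with entries in \{0, 1\};
#'   rownames are feature identifiers, colnames are drug identifiers.
#' @param feature_type one of `"chemical"`, `"domain"`, `"annotation"`.
#' @return a `drug_feature_table` object.
#' @export
feature_table <- function(values, feature_type = c("chemical", "domain", "annotation")) {
  feature_type <- match.arg(feature_type)
  values <- as.matrix(values)
  check_ids(rownames(values), "feature")
  check_ids(colnames(values), "drug")
  check_binary(values, "feature table")
  structure(values, class = c("drug_feature_table", class(values)),
            feature_type = feature_type)
}

#' Construct a similarity matrix over drugs or diseases
#'
#' Square, symmetric, entries in \[0, 1\], unit diagonal. Small asymmetries
#' (below `tol`) are repaired by averaging with the transpose; larger ones are
#' an error. The diagonal is forced to exactly 1 because every downstream use
#' assumes self-similarity 1.
#'
#' @param values square numeric matrix with matching row/col identifiers.
#' @param tol symmetry tolerance before averaging repair.
#' @return a `similarity_matrix` object.
#' @export
similarity_matrix <- function(values, tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square, got ", nrow(values), "x", ncol(values))
  check_ids(rownames(values), "entity")
  if (!is.null(colnames(values)) && !identical(rownames(values), colnames(values)))
    stop("similarity matrix row and column identifiers disagree")
  asym <- abs(values - t(values))
  if (any(asym > tol)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("similarity matrix asymmetric at (%s, %s): |%g - %g| > %g",
                 rownames(values)[ij[1]], rownames(values)[ij[2]],
                 values[ij[1], ij[2]], values[ij[2], ij[1]], tol))
  }
  values <- (values + t(values)) / 2
  check_range01(values, "similarity matrix")
  diag(values) <- 1
  structure(values, class = c("similarity_matrix", class(values)))
}

#' Construct a binary drug-disease association matrix
#'
#' Entries are 1 for a known association and 0 for an unknown pair (to be
#' predicted, not a confirmed negative).
#'
#' @param values numeric drugs-by-diseases matrix with entries in \{0, 1\};
#'   rownames are drug identifiers, colnames disease identifiers.
#' @return an `association_matrix` object.
#' @export
association_matrix <- function(values) {
  values <- as.matrix(values)
  check_ids(rownames(values), "drug")
  check_ids(colnames(values), "disease")
  check_binary(values, "association matrix")
  structure(values, class = c("association_matrix", class(values)))
}

check_ids <- function(ids, what) {
  if (is.null(ids)) stop("missing ", what, " identifiers (dimnames required)")
  if (anyDuplicated(ids))
    stop("duplicated ", what, " identifier: ", ids[duplicated(ids)][1])
  invisible(ids)
}

check_binary <- function(values, what) {
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    stop(sprintf("%s entry at (%s, %s) is %g; must be 0 or 1", what,
                 rownames(values)[ij[1]], colnames(values)[ij[2]],
                 values[ij[1], ij[2]]))
  }
  invisible(values)
}

check_range01 <- function(values, what) {
  bad <- which(values < 0 | values > 1)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    stop(sprintf("%s entry at (%s, %s) is %g; must lie in [0, 1]", what,
                 rownames(values)[ij[1]], colnames(values)[ij[2]],
                 values[ij[1], ij[2]]))
  }
  invisible(values)
}

#' Load a matrix from a tab-delimited file
#'
#' Expects a header row of column identifiers and a first column of row
#' identifiers; the body must be numeric. The returned object is validated
#' against the invariants of its kind: binary entries for `feature` and
#' `association`, symmetry / \[0,1\] range / unit diagonal for `similarity`.
#'
#' @param path file to read.
#' @param kind one of `"feature"`, `"similarity"`, `"association"`.
#' @param feature_type passed to [feature_table()] when `kind = "feature"`.
#' @return a [feature_table()], [similarity_matrix()] or
#'   [association_matrix()].
#' @export
load_matrix <- function(path, kind = c("feature", "similarity", "association"),
                        feature_type = "chemical") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("malformed matrix file (need row ids + data): ", path)
  row_ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body) & body != "NA")
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(body))
    stop(sprintf("cannot parse cell (row %s, column %s): '%s' is not numeric",
                 row_ids[ij[1]], colnames(body)[ij[2]], body[ij[1], ij[2]]))
  }
  if (anyNA(num)) {
    ij <- arrayInd(which(is.na(num))[1], dim(body))
    stop(sprintf("missing value at (row %s, column %s)", row_ids[ij[1]],
                 colnames(body)[ij[2]]))
  }
  dimnames(num) <- list(row_ids, colnames(body))
  switch(kind,
         feature = feature_table(num, feature_type),
         similarity = similarity_matrix(num),
         association = association_matrix(num))
}

#' Write a matrix in the package's tab-delimited dialect
#'
#' Inverse of [load_matrix()]: header row of column identifiers, first column
#' of row identifiers, values rendered with enough digits to round-trip.
#'
#' @param x a matrix with full dimnames.
#' @param path destination file.
#' @param id_header label for the identifier column in the header.
#' @export
write_matrix <- function(x, path, id_header = "id") {
  x <- as.matrix(x)
  body <- apply(x, 2, function(col) sprintf("%.12g", col))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
  lines <- c(paste(c(id_header, colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a score table
#'
#' One row per scored (drug, disease) pair with the fused association
#' probability and, when available, the known label.
#'
#' @param drug_id,disease_id character vectors.
#' @param score association scores in \[0, 1\].
#' @param known_label 0, 1, or `NA` for unknown.
#' @return a `data.frame` with class `score_table`.
#' @export
score_table <- function(drug_id = character(), disease_id = character(),
                        score = numeric(), known_label = NA) {
  if (length(score) && (any(score < 0) || any(score > 1)))
    stop("scores must lie in [0, 1]")
  df <- data.frame(drug_id = as.character(drug_id),
                   disease_id = as.character(disease_id),
                   score = as.numeric(score),
                   known_label = rep_len(known_label, length(score)),
                   stringsAsFactors = FALSE)
  class(df) <- c("score_table", class(df))
  df
}

#' Write a score table to a tab-delimited file
#'
#' @param scores a [score_table()].
#' @param path destination; the file has a header
#'   `drug_id  disease_id  score  known_label` and scores rendered with at
#'   least six significant digits.
#' @export
write_scores <- function(scores, path) {
  lines <- c("drug_id\tdisease_id\tscore\tknown_label",
             if (nrow(scores))
               sprintf("%s\t%s\t%.10g\t%s", scores$drug_id, scores$disease_id,
                       scores$score,
                       ifelse(is.na(scores$known_label), "unknown",
                              as.character(scores$known_label))))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path file to read.
#' @return a [score_table()].
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "character"))
  lab <- suppressWarnings(as.numeric(df$known_label))
  score_table(df$drug_id, df$disease_id, df$score, lab)
}

#' Align feature, similarity and association matrices on shared identifiers
#'
#' Restricts all inputs to the drugs present in every feature table and in the
#' association matrix, and to the diseases present in both the disease
#' similarity matrix and the association matrix, reordering everything to a
#' single shared ordering (the association matrix's order restricted to the
#' common sets). Aligning an already-aligned bundle is the identity.
#'
#' @param F1,F2,F3 [feature_table()]s (features x drugs).
#' @param D disease [similarity_matrix()].
#' @param A [association_matrix()] (drugs x diseases).
#' @return a list with elements `features` (list of the three tables), `D`,
#'   `A`, `drug_ids`, `disease_ids`, and `dropped` (counts per input).
#' @export
align_dataset <- function(F1, F2, F3, D, A) {
  feats <- list(F1, F2, F3)
  drug_sets <- c(lapply(feats, colnames), list(rownames(A)))
  drugs <- Reduce(intersect, drug_sets)
  diseases <- intersect(colnames(A), rownames(D))
  if (!length(drugs)) stop("no drug identifiers shared by all feature tables and the association matrix")
  if (!length(diseases)) stop("no disease identifiers shared by the disease similarity and association matrices")
  drugs <- rownames(A)[rownames(A) %in% drugs]       # A's order is canonical
  diseases <- colnames(A)[colnames(A) %in% diseases]
  dropped <- list(
    drugs = vapply(drug_sets, function(s) length(setdiff(s, drugs)), 0L),
    diseases = c(D = length(setdiff(rownames(D), diseases)),
                 A = length(setdiff(colnames(A), diseases))))
  feats_al <- lapply(feats, function(f)
    feature_table(unclass(f)[, drugs, drop = FALSE], attr(f, "feature_type")))
  names(feats_al) <- vapply(feats_al, attr, "", "feature_type")
  list(features = feats_al,
       D = similarity_matrix(unclass(D)[diseases, diseases, drop = FALSE]),
       A = association_matrix(unclass(A)[drugs, diseases, drop = FALSE]),
       drug_ids = drugs, disease_ids = diseases, dropped = dropped)
}
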