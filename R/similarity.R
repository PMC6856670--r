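# The four intra-drug similarity views.
#
# Views 1-3 are cosine similarities over binary feature profiles (chemical
# substructures, target-protein domains, target-protein annotations). View 4
# correlates two drugs through the diseases they are known to treat, using the
# intra-disease similarity matrix. View 4 depends on the association matrix,
# so cross-validation must recompute it from a masked copy (see
# mask_associations) to keep test labels out of the inputs.

#' Cosine similarity between drugs over one binary feature view
#'
#' For drugs i and j with feature indicator vectors f_i, f_j the similarity is
#' (f_i . f_j) / (||f_i|| ||f_j||). A drug with no features has undefined
#' cosine against everything; its off-diagonal similarities are set to 0 (no
#' evidence) and its diagonal to 1.
#'
#' @param F a [feature_table()] (features x drugs).
#' @return a drug [similarity_matrix()].
#' @export
cosine_similarity <- function(F) {
  V <- unclass(F)
  G <- crossprod(V)                       # co-occurrence counts, drugs x drugs
  nrm <- sqrt(diag(G))
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, G / denom, 0)
  S[S > 1] <- 1                           # guard float overshoot
  diag(S) <- 1
  similarity_matrix(S)
}

#' Drug similarity through correlated disease neighbourhoods
#'
#' Let DI_i be the set of diseases associated with drug i. For i != j with
#' both sets non-empty,
#'   R4(i, j) = ( sum_{k in DI_i} max_{d in DI_j} D(k, d)
#'              + sum_{k in DI_j} max_{d in DI_i} D(k, d) )
#'              / ( |DI_i| + |DI_j| ),
#' the average of each drug's diseases' best matches in the other drug's
#' disease set. If either set is empty the pair carries no disease evidence
#' and the similarity is 0. The diagonal is 1.
#'
#' @param A an [association_matrix()] (drugs x diseases).
#' @param D disease [similarity_matrix()] in A's disease ordering.
#' @return a drug [similarity_matrix()].
#' @export
disease_correlation_similarity <- function(A, D) {
  A <- unclass(A); D <- unclass(D)
  if (ncol(A) != nrow(D))
    stop("association matrix has ", ncol(A), " diseases but D has ", nrow(D))
  n_dr <- nrow(A)
  nb <- lapply(seq_len(n_dr), function(i) which(A[i, ] == 1))
  sizes <- lengths(nb)
  # best_match[k, j] = max_{d in DI_j} D(k, d); NA when DI_j is empty
  best_match <- vapply(nb, function(dj) {
    if (!length(dj)) return(rep(NA_real_, nrow(D)))
    do.call(pmax, c(lapply(dj, function(d) D[, d]), list(na.rm = FALSE)))
  }, numeric(nrow(D)))
  R <- diag(1, n_dr)
  for (i in seq_len(n_dr)) {
    if (!sizes[i]) next
    for (j in seq_len(n_dr)) {
      if (j >= i || !sizes[j]) next
      R[i, j] <- R[j, i] <-
        (sum(best_match[nb[[i]], j]) + sum(best_match[nb[[j]], i])) /
        (sizes[i] + sizes[j])
    }
  }
  dimnames(R) <- list(rownames(A), rownames(A))
  similarity_matrix(R)
}

#' Zero out selected association cells
#'
#' Returns a copy of the association matrix with each listed (drug, disease)
#' pair set to 0, leaving every other entry untouched. Used to hide a
#' cross-validation fold's test positives before recomputing the
#' disease-correlation similarity and before building embeddings, so a test
#' pair's own label never enters its input representation.
#'
#' @param A an [association_matrix()].
#' @param pairs two-column matrix or data frame of (drug index, disease index).
#' @return an [association_matrix()].
#' @export
mask_associations <- function(A, pairs) {
  vals <- unclass(A)
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  if (nrow(pairs)) {
    if (any(pairs[, 1] < 1L) || any(pairs[, 1] > nrow(vals)) ||
        any(pairs[, 2] < 1L) || any(pairs[, 2] > ncol(vals)))
      stop("pair index out of bounds for a ", nrow(vals), "x", ncol(vals),
           " association matrix")
    vals[pairs] <- 0
  }
  association_matrix(vals)
}
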