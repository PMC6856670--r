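# Heterogeneous pair embeddings.
#
# For a (drug i, disease k) pair, the network input is a 5 x (N_dr + N_di)
# matrix whose left block stacks drug-side rows (four similarity views plus
# the disease k association column, transposed) and whose right block stacks
# disease-side rows (drug i's association row repeated, plus disease k's
# similarity row):
#
#   row t (t = 1..4):  [ R_t(i, .) | A(i, .) ]
#   row 5:             [ A(., k)^T | D(k, .) ]
#
# The neighbour variant replaces each entity by its single most similar
# neighbour in the corresponding view, propagating association evidence
# through near neighbours.

#' Build the original heterogeneous pair embedding
#'
#' @param i drug index.
#' @param k disease index.
#' @param R list of the four drug [similarity_matrix()]s (chemical, domain,
#'   annotation, disease-correlation — in that order).
#' @param A [association_matrix()].
#' @param D disease [similarity_matrix()].
#' @return a `pair_embedding`: a 5 x (N_dr + N_di) matrix with attributes
#'   `drug_index`, `disease_index`, `variant = "original"`.
#' @export
build_hetero_matrix <- function(i, k, R, A, D) {
  A <- unclass(A); D <- unclass(D)
  n_dr <- nrow(A); n_di <- ncol(A)
  if (i < 1 || i > n_dr) stop("drug index ", i, " out of range [1, ", n_dr, "]")
  if (k < 1 || k > n_di) stop("disease index ", k, " out of range [1, ", n_di, "]")
  stopifnot(length(R) == 4)
  X <- rbind(
    cbind(matrix(vapply(R, function(r) unclass(r)[i, ], numeric(n_dr)),
                 nrow = 4, byrow = TRUE), matrix(A[i, ], 4, n_di, byrow = TRUE)),
    c(A[, k], D[k, ]))
  dimnames(X) <- NULL
  structure(X, class = c("pair_embedding", class(X)),
            drug_index = as.integer(i), disease_index = as.integer(k),
            variant = "original")
}

#' Most similar neighbour of a drug and of a disease per similarity view
#'
#' For drug i, the neighbour in each view is the argmax of that view's row
#' excluding the drug itself (the diagonal is 1 and would always win);
#' likewise for disease k in `D`. Ties are broken toward the smallest index.
#' If a row is identically zero off the diagonal there is no meaningful
#' neighbour and the entity falls back to itself, flagged in `degenerate`.
#'
#' @inheritParams build_hetero_matrix
#' @param D disease [similarity_matrix()].
#' @return list with drug neighbour indices `m`, `n`, `p`, `q` (views 1-4),
#'   disease neighbour `l`, and a logical `degenerate` vector of length 5.
#' @export
select_neighbors <- function(i, k, R, D) {
  pick <- function(row, self) {
    row[self] <- -Inf
    if (all(row <= 0)) return(c(self, TRUE))
    c(which.max(row), FALSE)   # which.max takes the first (smallest) maximiser
  }
  dr <- vapply(R, function(r) pick(unclass(r)[i, ], i), numeric(2))
  di <- pick(unclass(D)[k, ], k)
  list(m = as.integer(dr[1, 1]), n = as.integer(dr[1, 2]),
       p = as.integer(dr[1, 3]), q = as.integer(dr[1, 4]),
       l = as.integer(di[1]),
       degenerate = as.logical(c(dr[2, ], di[2])))
}

#' Build the neighbouring heterogeneous pair embedding
#'
#' Rows 1-4 are the neighbour drugs' similarity rows with their own
#' association rows on the right; row 5 is the neighbour disease's association
#' column and similarity row:
#'
#'   rows:  \[R_1(m,.) | A(m,.)\], \[R_2(n,.) | A(n,.)\],
#'          \[R_3(p,.) | A(p,.)\], \[R_4(q,.) | A(q,.)\],
#'          \[A(.,l)^T | D(l,.)\]
#'
#' `right_block = "drug_rows"` (default) uses each neighbour drug's own
#' association row as above. `right_block = "neighbor_drug_l"` is an
#' alternative layout that repeats the association row of the drug indexed by
#' the disease-neighbour index l in all four upper rows (only defined when
#' l <= N_dr).
#'
#' @param neighbors a [select_neighbors()] result.
#' @param right_block `"drug_rows"` or `"neighbor_drug_l"`.
#' @inheritParams build_hetero_matrix
#' @return a `pair_embedding` with `variant = "neighbor"`.
#' @export
build_neighbor_hetero_matrix <- function(i, k, neighbors, R, A, D,
                                         right_block = c("drug_rows", "neighbor_drug_l")) {
  right_block <- match.arg(right_block)
  A <- unclass(A); D <- unclass(D)
  n_dr <- nrow(A); n_di <- ncol(A)
  if (i < 1 || i > n_dr) stop("drug index ", i, " out of range [1, ", n_dr, "]")
  if (k < 1 || k > n_di) stop("disease index ", k, " out of range [1, ", n_di, "]")
  nb <- with(neighbors, c(m, n, p, q))
  l <- neighbors$l
  if (any(nb < 1 | nb > n_dr)) stop("neighbour drug index out of range")
  if (l < 1 || l > n_di) stop("neighbour disease index out of range")
  left <- matrix(0, 4, n_dr)
  for (t in 1:4) left[t, ] <- unclass(R[[t]])[nb[t], ]
  right <- switch(right_block,
    drug_rows = A[nb, , drop = FALSE],
    neighbor_drug_l = {
      if (l > n_dr) stop("right_block 'neighbor_drug_l' needs l <= N_dr, got l = ", l)
      matrix(A[l, ], 4, n_di, byrow = TRUE)
    })
  X <- rbind(cbind(left, right), c(A[, l], D[l, ]))
  dimnames(X) <- NULL
  structure(X, class = c("pair_embedding", class(X)),
            drug_index = as.integer(i), disease_index = as.integer(k),
            variant = "neighbor")
}

#' Precompute neighbour indices for all drugs and diseases
#'
#' Vectorised convenience around [select_neighbors()]: one row per drug with
#' the neighbour per view, and one entry per disease.
#'
#' @inheritParams build_hetero_matrix
#' @return list with `drug` (N_dr x 4 integer matrix) and `disease`
#'   (length-N_di integer vector).
#' @keywords internal
neighbor_tables <- function(R, D) {
  pick_all <- function(S) {
    S <- unclass(S)
    diag(S) <- -Inf
    idx <- max.col(S, ties.method = "first")
    none <- apply(S <= 0, 1, all)
    idx[none] <- which(none)
    idx
  }
  list(drug = vapply(R, pick_all, integer(nrow(unclass(R[[1]])))),
       disease = pick_all(D))
}

#' Build embedding tensors for a set of pairs
#'
#' Assembles the original and neighbour embeddings for each (drug, disease)
#' pair into 5 x width x 1 x B arrays ready for the convolutional branches.
#' Embeddings are materialised per call rather than for the full pair grid;
#' the full grid would need on the order of N_dr * N_di * 5 * (N_dr + N_di)
#' values.
#'
#' @param pairs two-column matrix/data frame of (drug index, disease index).
#' @inheritParams build_hetero_matrix
#' @param right_block passed to [build_neighbor_hetero_matrix()].
#' @return list of arrays `original` and `neighbor`, each 5 x (N_dr + N_di)
#'   x 1 x B.
#' @export
build_embedding_batch <- function(pairs, R, A, D,
                                  right_block = "drug_rows") {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  Av <- unclass(A); Dv <- unclass(D)
  n_dr <- nrow(Av); n_di <- ncol(Av)
  w <- n_dr + n_di
  B <- nrow(pairs)
  nt <- neighbor_tables(R, D)
  Rv <- lapply(R, unclass)
  orig <- array(0, c(5L, w, 1L, B))
  nbr <- array(0, c(5L, w, 1L, B))
  for (b in seq_len(B)) {
    i <- pairs[b, 1]; k <- pairs[b, 2]
    for (t in 1:4) {
      orig[t, , 1L, b] <- c(Rv[[t]][i, ], Av[i, ])
      j <- nt$drug[i, t]
      nbr[t, , 1L, b] <- c(Rv[[t]][j, ],
                           if (right_block == "drug_rows") Av[j, ]
                           else Av[nt$disease[k], ])
    }
    orig[5L, , 1L, b] <- c(Av[, k], Dv[k, ])
    l <- nt$disease[k]
    nbr[5L, , 1L, b] <- c(Av[, l], Dv[l, ])
  }
  list(original = orig, neighbor = nbr)
}
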