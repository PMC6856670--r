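# Independent brute-force reference implementations used as oracles.
# Deliberately naive (double loops, explicit padding, all-pairs counts) and
# kept free of any code path shared with the package internals.

oracle_cosine <- function(V) {
  n <- ncol(V)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ni <- sqrt(sum(V[, i]^2)); nj <- sqrt(sum(V[, j]^2))
    S[i, j] <- if (ni == 0 || nj == 0) 0 else sum(V[, i] * V[, j]) / (ni * nj)
  }
  diag(S) <- 1
  S
}

oracle_disease_correlation <- function(A, D) {
  n <- nrow(A)
  S <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    DIm <- which(A[i, ] == 1); DIn <- which(A[j, ] == 1)
    if (!length(DIm) || !length(DIn)) { S[i, j] <- 0; next }
    s1 <- 0
    for (k in DIm) s1 <- s1 + max(sapply(DIn, function(d) D[k, d]))
    s2 <- 0
    for (k in DIn) s2 <- s2 + max(sapply(DIm, function(d) D[k, d]))
    S[i, j] <- (s1 + s2) / (length(DIm) + length(DIn))
  }
  S
}

# Naive sliding-window convolution + ReLU; V (H, W, C), Wf (kh, kw, C, N).
oracle_conv_relu <- function(V, Wf, b) {
  if (is.matrix(V)) V <- array(V, c(dim(V), 1))
  H <- dim(V)[1]; W <- dim(V)[2]; C <- dim(V)[3]
  kh <- dim(Wf)[1]; kw <- dim(Wf)[2]; N <- dim(Wf)[4]
  l <- (kh - 1) / 2; p <- (kw - 1) / 2
  Vp <- array(0, c(H + 2 * l, W + 2 * p, C))
  Vp[l + seq_len(H), p + seq_len(W), ] <- V
  out <- array(0, c(H, W, N))
  for (n in seq_len(N)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- b[n]
    for (c in seq_len(C))
      acc <- acc + sum(Vp[i:(i + kh - 1), j:(j + kw - 1), c] * Wf[, , c, n])
    out[i, j, n] <- max(0, acc)
  }
  out
}

# Naive block-max pooling of an (H, W, N) stack with zero padding of ragged
# edges.
oracle_max_pool <- function(S, window = c(1, 2)) {
  if (is.matrix(S)) S <- array(S, c(dim(S), 1))
  nw <- window[1]; nl <- window[2]
  H <- dim(S)[1]; W <- dim(S)[2]; N <- dim(S)[3]
  Hq <- ceiling(H / nw); Wq <- ceiling(W / nl)
  Sp <- array(0, c(Hq * nw, Wq * nl, N))
  Sp[seq_len(H), seq_len(W), ] <- S
  out <- array(0, c(Hq, Wq, N))
  for (n in seq_len(N)) for (i in seq_len(Hq)) for (j in seq_len(Wq))
    out[i, j, n] <- max(Sp[((i - 1) * nw + 1):(i * nw),
                           ((j - 1) * nl + 1):(j * nl), n])
  out
}

# Full single-branch forward pass written independently, straight-line.
oracle_branch_forward <- function(X, state, config) {
  s1 <- oracle_conv_relu(X, state$W1, state$b1)
  s2 <- oracle_max_pool(s1, config$pool1_shape)
  s3 <- oracle_conv_relu(s2, state$W2, state$b2)
  s4 <- oracle_max_pool(s3, config$pool2_shape)
  u <- as.vector(s4)
  z <- as.vector(state$Wd %*% u) + as.vector(state$bd)
  e <- exp(z - max(z))
  list(u = u, h = e / sum(e))
}

# All-pairs Mann-Whitney AUC with half credit for ties.
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# PR AUC by explicit threshold enumeration over distinct scores (descending),
# rectangle integration against recall increments.
oracle_pr_auc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  n_pos <- sum(labels == 1)
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Fixed small toy dataset: 5 drugs x 4 diseases with distinct, hand-set
# similarity values so block positions are unambiguous in embedding tests.
toy_dataset <- function() {
  sym <- function(M) { M[lower.tri(M)] <- t(M)[lower.tri(M)]; diag(M) <- 1; M }
  ids_dr <- paste0("r", 1:5); ids_di <- paste0("d", 1:4)
  set.seed(401)
  mk <- function(seed) {
    set.seed(seed)
    M <- matrix(round(runif(25, 0.05, 0.95), 2), 5, 5)
    M <- sym(M); dimnames(M) <- list(ids_dr, ids_dr)
    similarity_matrix(M)
  }
  R <- lapply(1:4, function(t) mk(410 + t))
  Dm <- matrix(round(runif(16, 0.05, 0.95), 2), 4, 4)
  Dm <- sym(Dm); dimnames(Dm) <- list(ids_di, ids_di)
  Av <- matrix(c(1,0,0,1, 0,1,0,0, 1,0,1,0, 0,0,0,1, 0,1,1,0), 5, 4,
               byrow = TRUE, dimnames = list(ids_dr, ids_di))
  list(R = R, D = similarity_matrix(Dm), A = association_matrix(Av))
}

# Small synthetic bundle for quick pipeline tests.
tiny_bundle <- function(seed = 3L) {
  generate_synthetic(synthetic_spec(n_drugs = 18L, n_diseases = 12L,
                                    n_clusters = 2L,
                                    n_features = c(30L, 30L, 30L),
                                    seed = seed))
}

similarity_views <- function(bundle, A = bundle$A) {
  c(lapply(bundle$features, cosine_similarity),
    list(disease_correlation_similarity(A, bundle$D)))
}
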