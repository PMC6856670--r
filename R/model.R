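# Dual-branch convolutional model.
#
# Each branch runs conv(ReLU) -> max-pool -> conv(ReLU) -> max-pool over one
# pair embedding (the original and the neighbour variant respectively),
# flattens, applies dropout during training, and maps through a dense softmax
# head to a two-component score (P(associated), P(not associated)). The two
# branch scores are fused convexly with weight alpha, and training minimises
# the weighted squared error between each branch's softmax output and the
# one-hot label:
#
#   loss = alpha * ||h_L - y||^2 + (1 - alpha) * ||h_R - y||^2
#
# (mean over the batch). Because the loss decomposes, the branches are
# trained jointly but do not exchange gradients.

#' Model configuration
#'
#' @param n_filters1,n_filters2 filter counts of the two convolutions.
#' @param conv1_shape,conv2_shape filter (rows, columns); both must be odd so
#'   that same-size zero padding is integral.
#' @param pool1_shape,pool2_shape pooling window (rows, columns); stride
#'   equals the window.
#' @param alpha convex fusion weight of the original-embedding branch, in
#'   \[0, 1\].
#' @param dropout_rate dropout probability on the flattened features during
#'   training, in \[0, 1).
#' @param epochs,batch_size,learning_rate Adam training hyper-parameters.
#' @param seed integer seed controlling initialisation, batching and dropout.
#' @param neighbor_right_block layout of the neighbour embedding's upper right
#'   block; see [build_neighbor_hetero_matrix()].
#' @return a `model_config` list.
#' @export
model_config <- function(n_filters1 = 3L, n_filters2 = 6L,
                         conv1_shape = c(3L, 5L), conv2_shape = c(3L, 5L),
                         pool1_shape = c(1L, 2L), pool2_shape = c(1L, 2L),
                         alpha = 0.5, dropout_rate = 0.5,
                         epochs = 100L, batch_size = 32L,
                         learning_rate = 1e-3, seed = 1L,
                         neighbor_right_block = "drug_rows") {
  if (any(c(conv1_shape, conv2_shape) %% 2 == 0))
    stop("convolution filter dimensions must be odd for same-size padding")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)")
  structure(list(n_filters1 = as.integer(n_filters1),
                 n_filters2 = as.integer(n_filters2),
                 conv1_shape = as.integer(conv1_shape),
                 conv2_shape = as.integer(conv2_shape),
                 pool1_shape = as.integer(pool1_shape),
                 pool2_shape = as.integer(pool2_shape),
                 alpha = alpha, dropout_rate = dropout_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 neighbor_right_block = neighbor_right_block),
            class = "model_config")
}

# Flattened feature length after the two pool stages for a 5 x width input.
flatten_dim <- function(config, width) {
  h1 <- ceiling(5 / config$pool1_shape[1])
  w1 <- ceiling(width / config$pool1_shape[2])
  h2 <- ceiling(h1 / config$pool2_shape[1])
  w2 <- ceiling(w1 / config$pool2_shape[2])
  as.integer(h2 * w2 * config$n_filters2)
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Random small symmetric initialisation of one branch's parameters.
init_branch <- function(config, width) {
  k1 <- config$conv1_shape; k2 <- config$conv2_shape
  N1 <- config$n_filters1; N2 <- config$n_filters2
  M <- flatten_dim(config, width)
  list(W1 = glorot(c(k1[1], k1[2], 1L, N1), prod(k1), prod(k1) * N1),
       b1 = numeric(N1),
       W2 = glorot(c(k2[1], k2[2], N1, N2), prod(k2) * N1, prod(k2) * N2),
       b2 = numeric(N2),
       Wd = glorot(c(2L, M), M, 2L),
       bd = numeric(2L))
}

# Full forward pass of one branch over a batch tensor (5, width, 1, B).
# dropout_mask, when supplied, is a (B x M) multiplicative mask already
# scaled by 1/(1 - rate); NULL means inference (no dropout).
branch_forward_batch <- function(X, state, config, dropout_mask = NULL) {
  c1 <- conv_relu_forward(X, state$W1, state$b1)
  p1 <- max_pool_forward(c1$out, config$pool1_shape)
  c2 <- conv_relu_forward(p1$out, state$W2, state$b2)
  p2 <- max_pool_forward(c2$out, config$pool2_shape)
  d <- dim(p2$out); M <- prod(d[1:3]); B <- d[4]
  u <- t(matrix(p2$out, M, B))
  u_drop <- if (is.null(dropout_mask)) u else u * dropout_mask
  Z <- u_drop %*% t(state$Wd) + rep(state$bd, each = B)
  h <- softmax_rows(Z)
  list(h = h, u = u,
       cache = list(c1 = c1$cache, p1 = p1$cache, c2 = c2$cache,
                    p2 = p2$cache, u_drop = u_drop, h = h,
                    dropout_mask = dropout_mask, s4_dim = d))
}

# Backpropagate dL/dh through one branch; returns parameter gradients.
branch_backward_batch <- function(dh, state, cache) {
  h <- cache$h
  dZ <- h * (dh - rowSums(dh * h))          # softmax Jacobian, row-wise
  dWd <- crossprod(dZ, cache$u_drop)
  dbd <- colSums(dZ)
  du <- dZ %*% state$Wd
  if (!is.null(cache$dropout_mask)) du <- du * cache$dropout_mask
  dS4 <- array(t(du), cache$s4_dim)
  dc2 <- max_pool_backward(dS4, cache$p2)
  g2 <- conv_relu_backward(dc2, cache$c2, need_input_grad = TRUE)
  dp1 <- max_pool_backward(g2$dX, cache$p1)
  g1 <- conv_relu_backward(dp1, cache$c1, need_input_grad = FALSE)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db, Wd = dWd, bd = dbd)
}

#' Forward pass of one branch on a single pair embedding
#'
#' @param X a [build_hetero_matrix()] / [build_neighbor_hetero_matrix()]
#'   result (5 x width matrix).
#' @param state branch parameters as produced by training.
#' @param config a [model_config()].
#' @param training if `TRUE`, dropout is applied (consumes RNG draws).
#' @return list with `u` (flattened pooled features) and `h` (length-2 score:
#'   `h[1]` = P(associated), `h[2]` = P(not associated)).
#' @export
branch_forward <- function(X, state, config, training = FALSE) {
  Xb <- array(unclass(X), c(dim(X), 1L, 1L))
  M <- flatten_dim(config, ncol(X))
  if (ncol(state$Wd) != M)
    stop("branch state expects flattened length ", ncol(state$Wd),
         " but this input yields ", M)
  mask <- NULL
  if (training && config$dropout_rate > 0)
    mask <- matrix(stats::rbinom(M, 1, 1 - config$dropout_rate) /
                     (1 - config$dropout_rate), 1L, M)
  fw <- branch_forward_batch(Xb, state, config, mask)
  list(u = drop(fw$u), h = drop(fw$h))
}

#' Fuse the two branch scores
#'
#' Convex combination `h = alpha * h_L + (1 - alpha) * h_R`; both components
#' stay non-negative and sum to 1.
#'
#' @param h_L,h_R two-component branch scores (or B x 2 matrices).
#' @param alpha fusion weight in \[0, 1\].
#' @return fused score of the same shape.
#' @export
fuse_scores <- function(h_L, h_R, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * h_L + (1 - alpha) * h_R
}

#' Training loss for one pair
#'
#' Weighted squared error of both branch scores against the one-hot label:
#' `alpha * ||h_L - y||^2 + (1 - alpha) * ||h_R - y||^2`. The label is
#' `y = (1, 0)` for an associated pair and `y = (0, 1)` otherwise, matching
#' the score convention `h[1]` = P(associated).
#'
#' @param h_L,h_R two-component branch scores.
#' @param y one-hot label vector.
#' @param alpha fusion weight in \[0, 1\].
#' @return non-negative scalar loss.
#' @export
pair_loss <- function(h_L, h_R, y, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * sum((h_L - y)^2) + (1 - alpha) * sum((h_R - y)^2)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# Mean batch loss and per-branch parameter gradients for a labelled batch.
# XL, XR: (5, width, 1, B) tensors; Y: (B x 2) one-hot rows.
dual_step <- function(XL, XR, Y, left, right, config, masks = NULL) {
  B <- dim(XL)[4]
  fl <- branch_forward_batch(XL, left, config, masks$left)
  fr <- branch_forward_batch(XR, right, config, masks$right)
  a <- config$alpha
  loss <- mean(a * rowSums((fl$h - Y)^2) + (1 - a) * rowSums((fr$h - Y)^2))
  gl <- branch_backward_batch(2 * a * (fl$h - Y) / B, left, fl$cache)
  gr <- branch_backward_batch(2 * (1 - a) * (fr$h - Y) / B, right, fr$cache)
  list(loss = loss, grad_left = gl, grad_right = gr, h_L = fl$h, h_R = fr$h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Train the dual-branch model on labelled pair embeddings
#'
#' Minimises the weighted squared-error loss with Adam over shuffled
#' mini-batches. Initialisation, batch order and dropout are all driven by
#' `config$seed`, so identical seeds give identical trained models. Training
#' stops at `config$epochs` or earlier once the epoch-mean loss has plateaued
#' (spread below `plateau_tol` over five consecutive epochs).
#'
#' @param embeddings list with arrays `original` and `neighbor`, each
#'   (5, width, 1, B), e.g. from [build_embedding_batch()].
#' @param labels length-B vector in \{0, 1\}; 1 = associated.
#' @param config a [model_config()].
#' @param plateau_tol loss-spread tolerance for early stopping.
#' @param verbose print the epoch losses.
#' @return a `dualpairnet_model` with branch states `left` (original
#'   embedding) and `right` (neighbour embedding), the config, and the epoch
#'   loss history.
#' @export
train_dualcnn <- function(embeddings, labels, config = model_config(),
                          plateau_tol = 1e-7, verbose = FALSE) {
  XL <- embeddings$original; XR <- embeddings$neighbor
  B <- dim(XL)[4]
  labels <- as.integer(labels)
  if (length(labels) != B) stop("labels length != batch dimension")
  if (length(unique(labels)) < 2)
    stop("training set must contain both associated and unknown pairs")
  width <- dim(XL)[2]
  M <- flatten_dim(config, width)
  Y <- cbind(labels, 1L - labels, deparse.level = 0)
  with_seed(config$seed, {
    left <- init_branch(config, width)
    right <- init_branch(config, width)
    opt_l <- adam_new(left); opt_r <- adam_new(right)
    history <- numeric(0)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(B)
      starts <- seq(1L, B, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, B)]
        nb <- length(idx)
        masks <- NULL
        if (config$dropout_rate > 0) {
          keep <- 1 - config$dropout_rate
          masks <- list(
            left = matrix(stats::rbinom(nb * M, 1, keep) / keep, nb, M),
            right = matrix(stats::rbinom(nb * M, 1, keep) / keep, nb, M))
        }
        st <- dual_step(XL[, , , idx, drop = FALSE],
                        XR[, , , idx, drop = FALSE],
                        Y[idx, , drop = FALSE], left, right, config, masks)
        ep_loss <- ep_loss + st$loss * nb
        up <- adam_update(left, st$grad_left, opt_l, config$learning_rate)
        left <- up$params; opt_l <- up$opt
        up <- adam_update(right, st$grad_right, opt_r, config$learning_rate)
        right <- up$params; opt_r <- up$opt
      }
      history <- c(history, ep_loss / B)
      if (verbose) message(sprintf("epoch %3d  loss %.6f", ep, history[ep]))
      if (ep >= 5 && diff(range(history[(ep - 4):ep])) < plateau_tol) break
    }
    structure(list(config = config, width = width, flatten = M,
                   left = left, right = right, loss_history = history),
              class = "dualpairnet_model")
  })
}

#' @export
print.dualpairnet_model <- function(x, ...) {
  cat("dual-branch conv model: input 5 x", x$width,
      "| filters", x$config$n_filters1, "->", x$config$n_filters2,
      "| flattened", x$flatten,
      "| epochs run", length(x$loss_history),
      "| final loss", signif(utils::tail(x$loss_history, 1), 4), "\n")
  invisible(x)
}

#' Score (drug, disease) pairs with a trained model
#'
#' Builds both embeddings for every pair, runs the two branches with dropout
#' disabled, fuses the scores with the configured alpha and returns the fused
#' probability of association. Deterministic: repeated calls give identical
#' scores.
#'
#' @param model a trained [train_dualcnn()] model.
#' @param pairs two-column matrix/data frame of (drug index, disease index).
#' @param R list of the four drug similarity matrices.
#' @param A association matrix (masked appropriately by the caller).
#' @param D disease similarity matrix.
#' @param chunk forward-pass batch size.
#' @return numeric vector of scores in \[0, 1\].
#' @export
predict_pairs <- function(model, pairs, R, A, D, chunk = 512L) {
  if (is.null(model$left)) stop("model has no trained parameters")
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  n <- nrow(pairs)
  scores <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    emb <- build_embedding_batch(pairs[idx, , drop = FALSE], R, A, D,
                                 right_block = model$config$neighbor_right_block)
    hl <- branch_forward_batch(emb$original, model$left, model$config)$h
    hr <- branch_forward_batch(emb$neighbor, model$right, model$config)$h
    scores[idx] <- fuse_scores(hl, hr, model$config$alpha)[, 1]
  }
  scores
}

#' Score a single (drug, disease) pair
#'
#' @inheritParams predict_pairs
#' @param i drug index.
#' @param k disease index.
#' @return fused probability of association.
#' @export
predict_pair <- function(model, i, k, R, A, D) {
  predict_pairs(model, cbind(i, k), R, A, D)
}

#' Save a trained model as a self-describing JSON checkpoint
#'
#' @param model a `dualpairnet_model`.
#' @param path destination file.
#' @export
save_model <- function(model, path) {
  ser <- function(p) list(dim = dim(p) %||% length(p), values = as.vector(p))
  obj <- list(format = "dualpairnet-checkpoint-1",
              config = unclass(model$config),
              width = model$width, flatten = model$flatten,
              left = lapply(model$left, ser),
              right = lapply(model$right, ser),
              loss_history = model$loss_history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [save_model()].
#' @param width if given, the expected embedding width; a checkpoint trained
#'   on different dataset dimensions is rejected.
#' @return a `dualpairnet_model`.
#' @export
load_model <- function(path, width = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dualpairnet-checkpoint-1"))
    stop("not a recognised model checkpoint: ", path)
  if (!is.null(width) && obj$width != width)
    stop("checkpoint was trained for embedding width ", obj$width,
         " but the current dataset has width ", width)
  de <- function(p) if (length(p$dim) > 1) array(p$values, p$dim) else p$values
  cfg <- obj$config
  cfg <- model_config(cfg$n_filters1, cfg$n_filters2, cfg$conv1_shape,
                      cfg$conv2_shape, cfg$pool1_shape, cfg$pool2_shape,
                      cfg$alpha, cfg$dropout_rate, cfg$epochs, cfg$batch_size,
                      cfg$learning_rate, cfg$seed, cfg$neighbor_right_block)
  structure(list(config = cfg, width = obj$width, flatten = obj$flatten,
                 left = lapply(obj$left, de), right = lapply(obj$right, de),
                 loss_history = obj$loss_history),
            class = "dualpairnet_model")
}
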