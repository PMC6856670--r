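# Convolutional branches, fusion, loss, training and checkpoints.

test_that("convolution handles degenerate filters as ReLU dictates", {
  V <- matrix(runif(40), 5, 8)
  zf <- array(0, c(3, 5, 1, 1))
  expect_true(all(conv_relu(V, list(W = zf, b = 0)) == 0))
  expect_true(all(conv_relu(V, list(W = zf, b = -1)) == 0))
  expect_equal(unique(as.vector(conv_relu(V, list(W = zf, b = 0.7)))), 0.7)
})

test_that("convolution matches the sliding-window oracle", {
  set.seed(51)
  # single channel, one filter
  V <- matrix(runif(40, -1, 1), 5, 8)
  Wf <- array(runif(15, -1, 1), c(3, 5, 1, 1))
  expect_lt(max(abs(conv_relu(V, list(W = Wf, b = 0.2)) -
                    oracle_conv_relu(V, Wf, 0.2))), 1e-12)
  # multi-channel stacks as in the second layer
  V3 <- array(runif(5 * 12 * 3, -1, 1), c(5, 12, 3))
  Wf3 <- array(runif(3 * 5 * 3 * 6, -1, 1), c(3, 5, 3, 6))
  b3 <- runif(6, -0.5, 0.5)
  expect_lt(max(abs(conv_relu(V3, list(W = Wf3, b = b3)) -
                    oracle_conv_relu(V3, Wf3, b3))), 1e-12)
})

test_that("max pooling matches the block-max oracle", {
  expect_equal(as.vector(max_pool(matrix(c(1, 2, 5, 4), 1, 4))), c(2, 5))
  cm <- matrix(3.3, 5, 8)
  expect_true(all(max_pool(cm) == 3.3))
  expect_identical(dim(max_pool(cm)), c(5L, 4L, 1L))
  set.seed(52)
  S <- array(runif(5 * 12 * 4), c(5, 12, 4))
  for (win in list(c(1, 2), c(1, 3), c(2, 2), c(5, 2))) {
    expect_equal(max_pool(S, win), oracle_max_pool(S, win))
  }
  # odd width: ragged edge zero-padded
  S5 <- array(runif(5 * 5 * 2), c(5, 5, 2))
  expect_equal(max_pool(S5, c(1, 2)), oracle_max_pool(S5, c(1, 2)))
})

test_that("the branch forward pass equals a straight-line reference", {
  cfg <- model_config(seed = 1, dropout_rate = 0)
  set.seed(77)
  for (width in c(12, 20, 37)) {          # odd width exercises pool padding
    st <- dualpairnet:::init_branch(cfg, width)
    X <- matrix(runif(5 * width), 5, width)
    got <- branch_forward(X, st, cfg)
    ref <- oracle_branch_forward(array(X, c(5, width, 1)), st, cfg)
    expect_lt(max(abs(got$u - ref$u)), 1e-10)
    expect_lt(max(abs(got$h - ref$h)), 1e-10)
  }
})

test_that("branch scores are a probability pair", {
  cfg <- model_config(seed = 2, dropout_rate = 0)
  st <- dualpairnet:::init_branch(cfg, 16)
  set.seed(9)
  for (rep in 1:5) {
    h <- branch_forward(matrix(runif(80), 5, 16), st, cfg)$h
    expect_equal(sum(h), 1, tolerance = 1e-9)
    expect_true(all(h > 0))
  }
  st$Wd[] <- 0; st$bd[] <- 0
  h0 <- branch_forward(matrix(runif(80), 5, 16), st, cfg)$h
  expect_equal(h0, c(0.5, 0.5))
})

test_that("branch states reject inputs of the wrong width", {
  cfg <- model_config(seed = 2, dropout_rate = 0)
  st <- dualpairnet:::init_branch(cfg, 16)
  expect_error(branch_forward(matrix(0, 5, 24), st, cfg), "flattened length")
})

test_that("score fusion is the stated convex combination", {
  expect_equal(fuse_scores(c(0.8, 0.2), c(0.4, 0.6), 1), c(0.8, 0.2))
  expect_equal(fuse_scores(c(0.8, 0.2), c(0.4, 0.6), 0), c(0.4, 0.6))
  expect_equal(fuse_scores(c(0.8, 0.2), c(0.4, 0.6), 0.5), c(0.6, 0.4))
  expect_error(fuse_scores(c(1, 0), c(0, 1), 1.2), "alpha")
  set.seed(14)
  for (rep in 1:10) {
    a <- runif(1); p <- runif(1); q <- runif(1)
    h <- fuse_scores(c(p, 1 - p), c(q, 1 - q), a)
    expect_equal(sum(h), 1, tolerance = 1e-12)
    expect_true(all(h >= 0))
  }
})

test_that("the pair loss is the weighted squared error", {
  y <- c(1, 0)
  expect_equal(pair_loss(y, y, y, 0.3), 0)
  expect_equal(pair_loss(c(0.5, 0.5), c(0.9, 0.1), c(0, 1), 1), 0.5)
  set.seed(15)
  for (rep in 1:10) {
    hl <- runif(2); hr <- runif(2); a <- runif(1)
    y <- sample(list(c(1, 0), c(0, 1)), 1)[[1]]
    ref <- a * sum((hl - y)^2) + (1 - a) * sum((hr - y)^2)
    expect_equal(pair_loss(hl, hr, y, a), ref, tolerance = 1e-12)
  }
})

test_that("backpropagated gradients match finite differences", {
  cfg <- model_config(seed = 3, dropout_rate = 0, alpha = 0.4)
  width <- 14
  set.seed(90)
  left <- dualpairnet:::init_branch(cfg, width)
  right <- dualpairnet:::init_branch(cfg, width)
  XL <- array(runif(5 * width * 2), c(5, width, 1, 2))
  XR <- array(runif(5 * width * 2), c(5, width, 1, 2))
  Y <- rbind(c(1, 0), c(0, 1))
  st <- dualpairnet:::dual_step(XL, XR, Y, left, right, cfg)
  loss_at <- function(l, r) dualpairnet:::dual_step(XL, XR, Y, l, r, cfg)$loss
  # central differences, falling back to a 10x smaller step when the larger
  # one straddles a ReLU kink (a wrong gradient fails at both step sizes)
  rel_err <- function(params, nm, idx, an, branch) {
    err_at <- function(eps) {
      pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
      pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
      fd <- if (branch == "left")
        (loss_at(pp, right) - loss_at(pm, right)) / (2 * eps)
      else
        (loss_at(left, pp) - loss_at(left, pm)) / (2 * eps)
      abs(fd - an) / max(abs(fd), abs(an), 1e-8)
    }
    e <- err_at(1e-5)
    if (e > 1e-4) e <- min(e, err_at(1e-6))
    e
  }
  for (branch in c("left", "right")) {
    params <- get(branch)
    grads <- if (branch == "left") st$grad_left else st$grad_right
    for (nm in names(params)) {
      set.seed(91)
      for (probe in seq_len(min(4, length(params[[nm]])))) {
        idx <- sample(length(params[[nm]]), 1)
        expect_lt(rel_err(params, nm, idx, grads[[nm]][idx], branch), 1e-4)
      }
    }
  }
})

separable_embeddings <- function(n_pos = 20, n_neg = 20, width = 16) {
  set.seed(60)
  C1 <- matrix(runif(5 * width), 5, width)
  C2 <- matrix(runif(5 * width), 5, width)
  XL <- array(0, c(5, width, 1, n_pos + n_neg))
  for (b in seq_len(n_pos)) XL[, , 1, b] <- C1
  for (b in n_pos + seq_len(n_neg)) XL[, , 1, b] <- C2
  list(original = XL, neighbor = XL,
       labels = rep(c(1L, 0L), c(n_pos, n_neg)))
}

test_that("training drives the loss down on a separable toy problem", {
  sep <- separable_embeddings()
  cfg <- model_config(seed = 4, dropout_rate = 0, epochs = 200,
                      learning_rate = 5e-3, batch_size = 8)
  m <- train_dualcnn(sep[c("original", "neighbor")], sep$labels, cfg)
  expect_lt(tail(m$loss_history, 1), 0.05)
  expect_lte(length(m$loss_history), 200)
})

test_that("training is deterministic given the seed", {
  sep <- separable_embeddings()
  cfg <- model_config(seed = 5, epochs = 8)
  m1 <- train_dualcnn(sep[c("original", "neighbor")], sep$labels, cfg)
  m2 <- train_dualcnn(sep[c("original", "neighbor")], sep$labels, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$left, m2$left)
  expect_identical(m1$right, m2$right)
})

test_that("alpha = 1 makes the fused score the left branch's score", {
  sep <- separable_embeddings(6, 6)
  cfg <- model_config(seed = 6, alpha = 1, epochs = 5, dropout_rate = 0)
  m <- train_dualcnn(sep[c("original", "neighbor")], sep$labels, cfg)
  X <- sep$original[, , 1, 1]
  hl <- branch_forward(X, m$left, m$config)$h
  hr <- branch_forward(X, m$right, m$config)$h
  expect_equal(fuse_scores(hl, hr, 1), hl)
})

test_that("training rejects single-class data", {
  sep <- separable_embeddings(4, 4)
  expect_error(train_dualcnn(sep[c("original", "neighbor")],
                             rep(1L, 8), model_config(epochs = 1)),
               "both")
})

test_that("trained scores separate held-out constant-pattern pairs", {
  set.seed(61)
  width <- 16
  sep <- separable_embeddings(24, 24, width)
  train_idx <- c(1:20, 25:44)
  test_pos <- 21:24; test_neg <- 45:48
  sub <- function(a, idx) a[, , , idx, drop = FALSE]
  cfg <- model_config(seed = 7, dropout_rate = 0, epochs = 120,
                      learning_rate = 5e-3, batch_size = 8)
  m <- train_dualcnn(list(original = sub(sep$original, train_idx),
                          neighbor = sub(sep$neighbor, train_idx)),
                     sep$labels[train_idx], cfg)
  score_of <- function(idx) {
    X <- sep$original[, , 1, idx]
    fuse_scores(branch_forward(X, m$left, cfg)$h,
                branch_forward(X, m$right, cfg)$h, cfg$alpha)[1]
  }
  sp <- vapply(test_pos, score_of, 0)
  sn <- vapply(test_neg, score_of, 0)
  expect_true(min(sp) > max(sn))
  expect_true(all(c(sp, sn) >= 0 & c(sp, sn) <= 1))
  expect_identical(vapply(test_pos, score_of, 0), sp)  # inference deterministic
})

test_that("model checkpoints round-trip and reject mismatched dimensions", {
  sep <- separable_embeddings(6, 6)
  cfg <- model_config(seed = 8, epochs = 3)
  m <- train_dualcnn(sep[c("original", "neighbor")], sep$labels, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f, width = 16)
  expect_equal(m2$left, m$left, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m2$config$alpha, m$config$alpha)
  X <- sep$original[, , 1, 2]
  expect_equal(branch_forward(X, m2$left, m2$config)$h,
               branch_forward(X, m$left, m$config)$h, tolerance = 1e-12)
  expect_error(load_model(f, width = 99), "width")
})

test_that("configurations with even filters or bad rates are rejected", {
  expect_error(model_config(conv1_shape = c(2, 5)), "odd")
  expect_error(model_config(alpha = 1.5), "alpha")
  expect_error(model_config(dropout_rate = 1), "dropout")
})
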