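# Convolution, pooling and dense/softmax primitives.
#
# The batched conv/pool forward and backward passes run in compiled code
# (src/conv.cpp); tensors are base R arrays in (height, width, channels,
# batch) layout. Convolutions are stride-1 cross-correlations with implicit
# zero padding l = (kh-1)/2, p = (kw-1)/2 so that spatial size is preserved
# ("same" padding keeps the marginal information); pooling windows equal
# their stride, with ragged edges zero-padded (activations are non-negative
# after the ReLU, so padding never wins a max).

# Forward convolution with ReLU over a batch tensor.
# X: (H, W, C, B); W_f: (kh, kw, C, N) filters; b: length-N biases.
conv_relu_forward <- function(X, W_f, b) {
  kd <- dim(W_f)
  if (kd[1] %% 2 == 0 || kd[2] %% 2 == 0)
    stop("filter dimensions must be odd for same-size padding")
  if (kd[3] != dim(X)[3])
    stop("filter channel count ", kd[3], " != input channels ", dim(X)[3])
  if (kd[1] > dim(X)[1] + kd[1] - 1 || kd[2] > dim(X)[2] + kd[2] - 1)
    stop("filter larger than padded input")
  out <- cpp_conv_relu_fwd(X, W_f, b)
  list(out = out, cache = list(X = X, W = W_f, act = out))
}

# Gradients of the filters, biases and (optionally) the input.
conv_relu_backward <- function(d_out, cache, need_input_grad = TRUE) {
  cpp_conv_relu_bwd(d_out, cache$act, cache$X, cache$W, need_input_grad)
}

max_pool_forward <- function(X, window = c(1L, 2L)) {
  res <- cpp_pool_fwd(X, as.integer(window[1]), as.integer(window[2]))
  list(out = res$out,
       cache = list(arg = res$arg, in_dim = dim(X),
                    window = as.integer(window)))
}

max_pool_backward <- function(d_out, cache) {
  cpp_pool_bwd(d_out, cache$arg, as.integer(cache$in_dim),
               cache$window[1], cache$window[2])
}

# Row-wise numerically stable softmax of a (B x K) matrix.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Convolve feature maps with ReLU activation (single sample)
#'
#' Slides each filter over the zero-padded input with stride 1x1 so the
#' spatial size is preserved, adds the filter bias and applies a rectified
#' linear unit. The filter spans all input channels.
#'
#' @param V input: a matrix (single channel) or an (H, W, C) array.
#' @param filters list with `W` — a (kh, kw, C, N) array of N filters with odd
#'   kh, kw — and `b`, a length-N bias vector.
#' @return an (H, W, N) array of feature maps.
#' @export
conv_relu <- function(V, filters) {
  if (is.matrix(V)) V <- array(V, c(dim(V), 1L))
  W_f <- filters$W
  if (length(dim(W_f)) == 2) W_f <- array(W_f, c(dim(W_f), 1L, 1L))
  if (length(dim(W_f)) == 3) W_f <- array(W_f, c(dim(W_f), 1L))
  X <- array(V, c(dim(V), 1L))
  out <- conv_relu_forward(X, W_f, filters$b)$out
  array(out, dim(out)[1:3])
}

#' Max-pool a stack of feature maps (single sample)
#'
#' Non-overlapping (window = stride) max pooling; the default 1x2 window
#' halves the width and keeps the height. Odd extents are zero-padded.
#'
#' @param S an (H, W, N) array (or a matrix, treated as one map).
#' @param window integer pair (rows, columns).
#' @return pooled array of ceiling-divided spatial size.
#' @export
max_pool <- function(S, window = c(1L, 2L)) {
  if (is.matrix(S)) S <- array(S, c(dim(S), 1L))
  X <- array(S, c(dim(S), 1L))
  out <- max_pool_forward(X, as.integer(window))$out
  array(out, dim(out)[1:3])
}
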