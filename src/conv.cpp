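// Convolution and max-pooling kernels for the dual-branch network.
//
// Tensors arrive as R arrays in (height, width, channels, batch) layout,
// i.e. column-major with height fastest. Convolutions are stride-1
// cross-correlations with implicit zero padding l = (kh-1)/2, p = (kw-1)/2
// so spatial size is preserved; pooling windows equal their stride.

#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t at(int i, int j, int c, int b, int H, int W, int C) {
  return i + (R_xlen_t)H * (j + (R_xlen_t)W * (c + (R_xlen_t)C * b));
}

static NumericVector num4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector int4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Forward convolution + ReLU.
// X: (H, W, C, B); Wf: (kh, kw, C, N); b: length N. Returns (H, W, N, B).
// [[Rcpp::export]]
NumericVector cpp_conv_relu_fwd(NumericVector X, NumericVector Wf,
                                NumericVector bias) {
  IntegerVector xd = X.attr("dim"), wd = Wf.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], N = wd[3];
  if (wd[2] != C) stop("filter channels do not match input channels");
  int l = (kh - 1) / 2, p = (kw - 1) / 2;
  NumericVector out = num4(H, W, N, B);
  const double *x = X.begin(), *w = Wf.begin();
  double *o = out.begin();
  for (int b = 0; b < B; ++b)
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double acc = bias[n];
          for (int c = 0; c < C; ++c)
            for (int dj = 0; dj < kw; ++dj) {
              int xj = j + dj - p;
              if (xj < 0 || xj >= W) continue;
              for (int di = 0; di < kh; ++di) {
                int xi = i + di - l;
                if (xi < 0 || xi >= H) continue;
                acc += x[at(xi, xj, c, b, H, W, C)] *
                       w[di + kh * (dj + kw * (c + C * (R_xlen_t)n))];
              }
            }
          o[at(i, j, n, b, H, W, N)] = acc > 0 ? acc : 0;
        }
  return out;
}

// Backward pass: d_out is the gradient w.r.t. the ReLU output, act the
// forward activations (used as the ReLU mask: gradient flows where act > 0).
// Returns dW, db and, when need_input_grad, dX.
// [[Rcpp::export]]
List cpp_conv_relu_bwd(NumericVector d_out, NumericVector act,
                       NumericVector X, NumericVector Wf,
                       bool need_input_grad) {
  IntegerVector xd = X.attr("dim"), wd = Wf.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], N = wd[3];
  int l = (kh - 1) / 2, p = (kw - 1) / 2;
  NumericVector dW = num4(kh, kw, C, N), db(N);
  NumericVector dX;
  if (need_input_grad) dX = num4(H, W, C, B);
  const double *x = X.begin(), *w = Wf.begin(), *g = d_out.begin(),
               *a = act.begin();
  double *dw = dW.begin(), *dx = need_input_grad ? dX.begin() : nullptr;
  for (int b = 0; b < B; ++b)
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          R_xlen_t oi = at(i, j, n, b, H, W, N);
          if (a[oi] <= 0) continue;
          double dz = g[oi];
          if (dz == 0) continue;
          db[n] += dz;
          for (int c = 0; c < C; ++c)
            for (int dj = 0; dj < kw; ++dj) {
              int xj = j + dj - p;
              if (xj < 0 || xj >= W) continue;
              for (int di = 0; di < kh; ++di) {
                int xi = i + di - l;
                if (xi < 0 || xi >= H) continue;
                R_xlen_t xidx = at(xi, xj, c, b, H, W, C);
                R_xlen_t widx = di + kh * (dj + kw * (c + C * (R_xlen_t)n));
                dw[widx] += dz * x[xidx];
                if (dx) dx[xidx] += dz * w[widx];
              }
            }
        }
  List res = List::create(_["dW"] = dW, _["db"] = db);
  if (need_input_grad) res["dX"] = dX;
  return res;
}

// Max pooling with an (nw, nl) window and matching stride; ragged edges are
// zero-padded (activations are non-negative post-ReLU, so padding never
// wins). Returns the pooled tensor and the 1-based within-window argmax
// (first maximiser wins ties, windows scanned column by column).
// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector X, int nw, int nl) {
  IntegerVector xd = X.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Hq = (H + nw - 1) / nw, Wq = (W + nl - 1) / nl;
  NumericVector out = num4(Hq, Wq, C, B);
  IntegerVector arg = int4(Hq, Wq, C, B);
  const double *x = X.begin();
  double *o = out.begin();
  int *am = arg.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int jq = 0; jq < Wq; ++jq)
        for (int iq = 0; iq < Hq; ++iq) {
          double best = R_NegInf;
          int besta = 0, cell = 0;
          for (int dj = 0; dj < nl; ++dj)
            for (int di = 0; di < nw; ++di) {
              ++cell;
              int i = iq * nw + di, j = jq * nl + dj;
              double v = (i < H && j < W) ? x[at(i, j, c, b, H, W, C)] : 0.0;
              if (v > best) { best = v; besta = cell; }
            }
          R_xlen_t oi = at(iq, jq, c, b, Hq, Wq, C);
          o[oi] = best;
          am[oi] = besta;
        }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// Backward max pooling: route each pooled gradient to its argmax cell.
// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector d_out, IntegerVector arg,
                           IntegerVector in_dim, int nw, int nl) {
  IntegerVector od = d_out.attr("dim");
  int Hq = od[0], Wq = od[1], C = od[2], B = od[3];
  int H = in_dim[0], W = in_dim[1];
  NumericVector dX = num4(H, W, C, B);
  const double *g = d_out.begin();
  const int *am = arg.begin();
  double *dx = dX.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int jq = 0; jq < Wq; ++jq)
        for (int iq = 0; iq < Hq; ++iq) {
          R_xlen_t oi = at(iq, jq, c, b, Hq, Wq, C);
          int cell = am[oi];
          if (cell == 0) continue;
          int dj = (cell - 1) / nw, di = (cell - 1) % nw;
          int i = iq * nw + di, j = jq * nl + dj;
          if (i < H && j < W)
            dx[at(i, j, c, b, H, W, C)] += g[oi];
        }
  return dX;
}
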