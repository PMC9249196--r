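// Streaming kernels for the network engine: im2col gather / col2im scatter,
// depthwise convolution, ceil-mode 2x2 max pooling, per-image layout
// permutes, and fused per-channel affine / leaky-ReLU passes. These are the
// memory-bound operations; the heavy linear algebra stays in BLAS on the R
// side. All loops work on raw REAL()/INTEGER() pointers.

#include <Rcpp.h>
using namespace Rcpp;

// Depthwise k x k convolution over a padded activation matrix.
// Xp: (Hp*Wp*C) x N padded batch, column-major images with rows fastest.
// W: C x (k*k) per-channel kernels (tap order: kh fastest, then kw).
// [[Rcpp::export]]
NumericMatrix cpp_dw_forward(NumericMatrix Xp, NumericMatrix W,
                             NumericVector b, int H, int Wd, int C, int k) {
  const int p = (k - 1) / 2;
  const int Hp = H + 2 * p, Wp = Wd + 2 * p;
  const int N = Xp.ncol();
  NumericMatrix Y(H * Wd * C, N);
  const double* xb = REAL(Xp);
  const double* wb = REAL(W);
  const double* bb = REAL(b);
  double* yb = REAL(Y);
  const R_xlen_t xcolsz = (R_xlen_t)Hp * Wp * C;
  const R_xlen_t ycolsz = (R_xlen_t)H * Wd * C;
  for (int n = 0; n < N; ++n) {
    const double* x = xb + n * xcolsz;
    double* y = yb + n * ycolsz;
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (R_xlen_t)c * Hp * Wp;
      double* yc = y + (R_xlen_t)c * H * Wd;
      const double bc = bb[c];
      for (R_xlen_t i = 0; i < (R_xlen_t)H * Wd; ++i) yc[i] = bc;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          const double w = wb[c + (R_xlen_t)C * (kh + k * kw)];
          if (w == 0.0) continue;
          for (int ow = 0; ow < Wd; ++ow) {
            const double* __restrict__ xo = xc + (R_xlen_t)(ow + kw) * Hp + kh;
            double* __restrict__ yo = yc + (R_xlen_t)ow * H;
            for (int oh = 0; oh < H; ++oh) yo[oh] += w * xo[oh];
          }
        }
      }
    }
  }
  return Y;
}

// Gradients of the depthwise layer: weight/bias gradients and the gradient
// with respect to the padded input.
// [[Rcpp::export]]
List cpp_dw_backward(NumericMatrix Xp, NumericMatrix dY, NumericMatrix W,
                     int H, int Wd, int C, int k) {
  const int p = (k - 1) / 2;
  const int Hp = H + 2 * p, Wp = Wd + 2 * p;
  const int N = Xp.ncol();
  NumericMatrix dW(C, k * k);
  NumericVector db(C);
  NumericMatrix dXp(Hp * Wp * C, N);
  const double* xb = REAL(Xp);
  const double* dyb = REAL(dY);
  const double* wb = REAL(W);
  double* dwb = REAL(dW);
  double* dbb = REAL(db);
  double* dxb = REAL(dXp);
  const R_xlen_t xcolsz = (R_xlen_t)Hp * Wp * C;
  const R_xlen_t ycolsz = (R_xlen_t)H * Wd * C;
  for (int n = 0; n < N; ++n) {
    const double* x = xb + n * xcolsz;
    const double* dy = dyb + n * ycolsz;
    double* dx = dxb + n * xcolsz;
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (R_xlen_t)c * Hp * Wp;
      const double* dyc = dy + (R_xlen_t)c * H * Wd;
      double* dxc = dx + (R_xlen_t)c * Hp * Wp;
      double acc_b = 0.0;
      for (R_xlen_t i = 0; i < (R_xlen_t)H * Wd; ++i) acc_b += dyc[i];
      dbb[c] += acc_b;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          const double w = wb[c + (R_xlen_t)C * (kh + k * kw)];
          double acc_w = 0.0;
          for (int ow = 0; ow < Wd; ++ow) {
            const double* __restrict__ xo = xc + (R_xlen_t)(ow + kw) * Hp + kh;
            const double* __restrict__ dyo = dyc + (R_xlen_t)ow * H;
            double* __restrict__ dxo = dxc + (R_xlen_t)(ow + kw) * Hp + kh;
            for (int oh = 0; oh < H; ++oh) {
              acc_w += dyo[oh] * xo[oh];
              dxo[oh] += w * dyo[oh];
            }
          }
          dwb[c + (R_xlen_t)C * (kh + k * kw)] += acc_w;
        }
      }
    }
  }
  return List::create(Named("dW") = dW, Named("db") = db,
                      Named("dXp") = dXp);
}

// Row gather: out[i, n] = X[idx[i] - 1, n]; idx == 0 yields 0 (zero
// padding). The im2col workhorse.
// [[Rcpp::export]]
NumericMatrix cpp_gather(NumericMatrix X, IntegerVector idx) {
  const int N = X.ncol();
  const R_xlen_t M = idx.size(), nr = X.nrow();
  NumericMatrix out(M, N);
  const int* id = INTEGER(idx);
  const double* xb = REAL(X);
  double* ob = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* x = xb + n * nr;
    double* o = ob + n * M;
    for (R_xlen_t i = 0; i < M; ++i) o[i] = id[i] ? x[id[i] - 1] : 0.0;
  }
  return out;
}

// Gather into a preallocated workspace (first X.ncol() columns of out), so
// large im2col buffers are reused across batches instead of reallocated.
// [[Rcpp::export]]
void cpp_gather_into(NumericMatrix X, IntegerVector idx, NumericMatrix out) {
  const int N = X.ncol();
  const R_xlen_t M = idx.size(), nr = X.nrow();
  const int* id = INTEGER(idx);
  const double* xb = REAL(X);
  double* ob = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* x = xb + n * nr;
    double* o = ob + n * M;
    for (R_xlen_t i = 0; i < M; ++i) o[i] = id[i] ? x[id[i] - 1] : 0.0;
  }
}

// Row scatter-add: out[idx[i] - 1, n] += X[i, n]; idx == 0 entries are
// dropped. The col2im workhorse.
// [[Rcpp::export]]
NumericMatrix cpp_scatter_add(NumericMatrix X, IntegerVector idx,
                              int nrow_out) {
  const int N = X.ncol();
  const R_xlen_t M = idx.size();
  NumericMatrix out(nrow_out, N);
  const int* id = INTEGER(idx);
  const double* xb = REAL(X);
  double* ob = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* x = xb + n * M;
    double* o = ob + (R_xlen_t)n * nrow_out;
    for (R_xlen_t i = 0; i < M; ++i) {
      if (id[i]) o[id[i] - 1] += x[i];
    }
  }
  return out;
}

// Per-image layout permute, (F, HW*N) -> (HW*F, N): channel-major GEMM
// output back to the engine's row-fastest activation layout.
// [[Rcpp::export]]
NumericMatrix cpp_to_act(NumericMatrix Y, int F, int HW) {
  const int N = Y.ncol() * Y.nrow() / (F * HW);
  NumericMatrix out((R_xlen_t)HW * F, N);
  const double* yb = REAL(Y);
  double* ob = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* y = yb + (R_xlen_t)n * F * HW;
    double* o = ob + (R_xlen_t)n * HW * F;
    for (int pos = 0; pos < HW; ++pos) {
      const double* yp = y + (R_xlen_t)pos * F;
      for (int f = 0; f < F; ++f) o[(R_xlen_t)f * HW + pos] = yp[f];
    }
  }
  return out;
}

// Inverse permute, (HW*F, N) -> (F, HW*N).
// [[Rcpp::export]]
NumericMatrix cpp_from_act(NumericMatrix X, int F, int HW) {
  const int N = X.ncol();
  NumericMatrix out(F, (R_xlen_t)HW * N);
  const double* xb = REAL(X);
  double* ob = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* x = xb + (R_xlen_t)n * HW * F;
    double* o = ob + (R_xlen_t)n * F * HW;
    for (int pos = 0; pos < HW; ++pos) {
      double* op = o + (R_xlen_t)pos * F;
      for (int f = 0; f < F; ++f) op[f] = x[(R_xlen_t)f * HW + pos];
    }
  }
  return out;
}

// Ceil-mode 2x2/stride-2 max pooling. idx: OUT x 4 candidate source rows
// (1-based; 0 marks an out-of-range candidate). Returns the pooled batch and
// the winning candidate per output element (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericMatrix X, IntegerMatrix idx) {
  const int N = X.ncol();
  const int OUT = idx.nrow();
  const R_xlen_t nr = X.nrow();
  NumericMatrix Y(OUT, N);
  IntegerMatrix arg(OUT, N);
  const double* xb = REAL(X);
  const int* id = INTEGER(idx);
  double* yb = REAL(Y);
  int* ab = INTEGER(arg);
  for (int n = 0; n < N; ++n) {
    const double* x = xb + n * nr;
    double* y = yb + (R_xlen_t)n * OUT;
    int* a = ab + (R_xlen_t)n * OUT;
    for (int j = 0; j < OUT; ++j) {
      double best = R_NegInf;
      int bk = 1;
      for (int k = 0; k < 4; ++k) {
        const int src = id[j + (R_xlen_t)k * OUT];
        if (src == 0) continue;
        const double v = x[src - 1];
        if (v > best) {
          best = v;
          bk = k + 1;
        }
      }
      y[j] = best;
      a[j] = bk;
    }
  }
  return List::create(Named("Y") = Y, Named("arg") = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_backward(NumericMatrix dY, IntegerMatrix arg,
                                   IntegerMatrix idx, int nrow_in) {
  const int N = dY.ncol();
  const int OUT = idx.nrow();
  NumericMatrix dX(nrow_in, N);
  const double* dyb = REAL(dY);
  const int* ab = INTEGER(arg);
  const int* id = INTEGER(idx);
  double* dxb = REAL(dX);
  for (int n = 0; n < N; ++n) {
    const double* dy = dyb + (R_xlen_t)n * OUT;
    const int* a = ab + (R_xlen_t)n * OUT;
    double* dx = dxb + (R_xlen_t)n * nrow_in;
    for (int j = 0; j < OUT; ++j) {
      const int src = id[j + (R_xlen_t)(a[j] - 1) * OUT];
      if (src > 0) dx[src - 1] += dy[j];
    }
  }
  return dX;
}

// Fused per-channel affine pass: out[i, n] = a[c] * X[i, n] + b[c] with
// c = i / HW — one traversal for batch-norm scale/shift.
// [[Rcpp::export]]
NumericMatrix cpp_affine_group(NumericMatrix X, NumericVector a,
                               NumericVector b, int HW) {
  const int N = X.ncol();
  const R_xlen_t nr = X.nrow();
  const int C = nr / HW;
  NumericMatrix out(nr, N);
  const double* xb = REAL(X);
  const double* ab = REAL(a);
  const double* bb = REAL(b);
  double* ob = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* x = xb + n * nr;
    double* o = ob + n * nr;
    for (int c = 0; c < C; ++c) {
      const double ac = ab[c], bc = bb[c];
      const double* xc = x + (R_xlen_t)c * HW;
      double* oc = o + (R_xlen_t)c * HW;
      for (int i = 0; i < HW; ++i) oc[i] = ac * xc[i] + bc;
    }
  }
  return out;
}

// Leaky ReLU forward; the sign pattern is recoverable from the output, so no
// mask needs storing (slope < 1).
// [[Rcpp::export]]
NumericMatrix cpp_leaky(NumericMatrix X, double slope) {
  const R_xlen_t L = (R_xlen_t)X.nrow() * X.ncol();
  NumericMatrix out(X.nrow(), X.ncol());
  const double* x = REAL(X);
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < L; ++i) o[i] = x[i] > 0 ? x[i] : slope * x[i];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_leaky_grad(NumericMatrix Y, NumericMatrix dY, double slope) {
  const R_xlen_t L = (R_xlen_t)Y.nrow() * Y.ncol();
  NumericMatrix out(Y.nrow(), Y.ncol());
  const double* y = REAL(Y);
  const double* dy = REAL(dY);
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < L; ++i) o[i] = y[i] > 0 ? dy[i] : slope * dy[i];
  return out;
}

// Per-channel sum and sum of squares in one pass (batch-norm statistics).
// [[Rcpp::export]]
List cpp_group_moments(NumericMatrix X, int HW) {
  const int N = X.ncol();
  const R_xlen_t nr = X.nrow();
  const int C = nr / HW;
  NumericVector s(C), s2(C);
  const double* xb = REAL(X);
  double* sp = REAL(s);
  double* s2p = REAL(s2);
  for (int n = 0; n < N; ++n) {
    const double* x = xb + n * nr;
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (R_xlen_t)c * HW;
      double a = 0.0, a2 = 0.0;
      for (int i = 0; i < HW; ++i) {
        a += xc[i];
        a2 += xc[i] * xc[i];
      }
      sp[c] += a;
      s2p[c] += a2;
    }
  }
  return List::create(Named("sum") = s, Named("sumsq") = s2);
}

// Per-channel <dY> and <dY * xhat> in one pass (batch-norm gradients).
// [[Rcpp::export]]
List cpp_group_dots(NumericMatrix dY, NumericMatrix xhat, int HW) {
  const int N = dY.ncol();
  const R_xlen_t nr = dY.nrow();
  const int C = nr / HW;
  NumericVector sb(C), sg(C);
  const double* dyb = REAL(dY);
  const double* xhb = REAL(xhat);
  double* b = REAL(sb);
  double* g = REAL(sg);
  for (int n = 0; n < N; ++n) {
    const double* dy = dyb + n * nr;
    const double* xh = xhb + n * nr;
    for (int c = 0; c < C; ++c) {
      const double* dyc = dy + (R_xlen_t)c * HW;
      const double* xhc = xh + (R_xlen_t)c * HW;
      double ab = 0.0, ag = 0.0;
      for (int i = 0; i < HW; ++i) {
        ab += dyc[i];
        ag += dyc[i] * xhc[i];
      }
      b[c] += ab;
      g[c] += ag;
    }
  }
  return List::create(Named("dbeta") = sb, Named("dgamma") = sg);
}

// Fused batch-norm input gradient: out = A[c] * dY + B[c] * xhat + D[c].
// [[Rcpp::export]]
NumericMatrix cpp_bn_dx(NumericMatrix dY, NumericMatrix xhat, NumericVector A,
                        NumericVector B, NumericVector D, int HW) {
  const int N = dY.ncol();
  const R_xlen_t nr = dY.nrow();
  const int C = nr / HW;
  NumericMatrix out(nr, N);
  const double* dyb = REAL(dY);
  const double* xhb = REAL(xhat);
  const double* Ab = REAL(A);
  const double* Bb = REAL(B);
  const double* Db = REAL(D);
  double* ob = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* dy = dyb + n * nr;
    const double* xh = xhb + n * nr;
    double* o = ob + n * nr;
    for (int c = 0; c < C; ++c) {
      const double a = Ab[c], bc = Bb[c], d = Db[c];
      const double* dyc = dy + (R_xlen_t)c * HW;
      const double* xhc = xh + (R_xlen_t)c * HW;
      double* oc = o + (R_xlen_t)c * HW;
      for (int i = 0; i < HW; ++i) oc[i] = a * dyc[i] + bc * xhc[i] + d;
    }
  }
  return out;
}
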