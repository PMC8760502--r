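// Hot layers of the 1-D CNN: "same"-padded temporal convolution (im2col +
// BLAS gemm), batch normalization, ReLU and max/average pooling, forward and
// backward.  Activations are R arrays dim c(B, T, C), column-major, so one
// channel is a contiguous block of M = B*T doubles and a time shift is a
// stride of B within the block.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

static inline IntegerVector dims3(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  return d;
}

// C := alpha * op(A) %*% op(B) + beta * C, column-major with leading
// dimensions, straight onto the R arrays (no intermediate copies)
static inline void gemm(char ta, char tb, int m, int n, int k, double alpha,
                        const double* A, int lda, const double* B, int ldb,
                        double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

// "Same"-padded temporal convolution as k accumulated gemms: a time shift
// of dt is a row offset of B*dt inside the (B*T, C) column-major view of the
// activation array, so each kernel tap multiplies a contiguous row range of
// x by one C x Cout block of W with leading-dimension tricks and no im2col.

// [[Rcpp::export(name = ".conv1d_fw")]]
NumericVector conv1d_fw(NumericVector x, NumericMatrix W, NumericVector b,
                        int k) {
  IntegerVector d = dims3(x);
  const int B = d[0], T = d[1], C = d[2];
  const int Cout = W.ncol(), kC = W.nrow();
  if (kC != k * C) stop("weight rows must equal k * C_in");
  const int M = B * T, pl = (k - 1) / 2;
  NumericVector y(Dimension(B, T, Cout));
  for (int c = 0; c < Cout; ++c) {
    double* yc = y.begin() + (size_t)M * c;
    const double bc = b[c];
    for (int i = 0; i < M; ++i) yc[i] = bc;
  }
  if (C == 1) {
    // single-channel stem: one fused pass per output channel instead of k
    // rank-1 gemm updates over the full activation
    const double* xp = x.begin();
    for (int c = 0; c < Cout; ++c) {
      double* yc = y.begin() + (size_t)M * c;
      for (int j = 0; j < k; ++j) {
        const int dt = j - pl;
        const double w = W(j, c);
        const int t0 = std::max(0, -dt), t1 = std::min(T - 1, T - 1 - dt);
        const double* xs = xp + (size_t)(t0 + dt) * B;
        double* ys = yc + (size_t)t0 * B;
        const int len = (t1 - t0 + 1) * B;
        for (int i = 0; i < len; ++i) ys[i] += w * xs[i];
      }
    }
    return y;
  }
  // tile the row range so x and y stay cache-resident across the k taps
  const int BLK = 8192;
  for (int r0 = 0; r0 < M; r0 += BLK) {
    const int r1 = std::min(M, r0 + BLK);
    for (int j = 0; j < k; ++j) {
      const int dt = j - pl;
      const int lo = std::max(r0, std::max(0, -dt) * B);
      const int hi = std::min(r1, (std::min(T - 1, T - 1 - dt) + 1) * B);
      if (hi <= lo) continue;
      gemm('N', 'N', hi - lo, Cout, C, 1.0,
           x.begin() + (size_t)lo + (size_t)dt * B, M,
           W.begin() + j * C, kC,
           1.0, y.begin() + (size_t)lo, M);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv1d_bw")]]
List conv1d_bw(NumericVector x, NumericMatrix W, NumericVector dout, int k,
               bool need_dx) {
  IntegerVector d = dims3(x);
  const int B = d[0], T = d[1], C = d[2];
  const int Cout = W.ncol(), kC = W.nrow();
  const int M = B * T, pl = (k - 1) / 2;
  NumericMatrix dW(kC, Cout);
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* dc = dout.begin() + (size_t)M * c;
    double s = 0;
    for (int i = 0; i < M; ++i) s += dc[i];
    db[c] = s;
  }
  if (C == 1) {
    // fused single-channel stem: one pass per output channel for dW, one
    // pass over positions for dx (all taps in registers)
    const double* xp = x.begin();
    std::vector<double> acc(k);
    for (int c = 0; c < Cout; ++c) {
      const double* dc = dout.begin() + (size_t)M * c;
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int j = 0; j < k; ++j) {
        const int dt = j - pl;
        const int t0 = std::max(0, -dt), t1 = std::min(T - 1, T - 1 - dt);
        const double* ds = dc + (size_t)t0 * B;
        const double* xs = xp + (size_t)(t0 + dt) * B;
        const int len = (t1 - t0 + 1) * B;
        double s = 0;
        for (int i = 0; i < len; ++i) s += xs[i] * ds[i];
        acc[j] = s;
      }
      for (int j = 0; j < k; ++j) dW(j, c) = acc[j];
    }
    if (!need_dx) {
      return List::create(_["dx"] = R_NilValue, _["W"] = dW, _["b"] = db);
    }
    NumericVector dx(Dimension(B, T, 1));
    double* dd = dx.begin();
    for (int c = 0; c < Cout; ++c) {
      const double* dc = dout.begin() + (size_t)M * c;
      for (int j = 0; j < k; ++j) {
        const int dt = j - pl;
        const double w = W(j, c);
        const int t0 = std::max(0, -dt), t1 = std::min(T - 1, T - 1 - dt);
        const double* ds = dc + (size_t)t0 * B;
        double* dp = dd + (size_t)(t0 + dt) * B;
        const int len = (t1 - t0 + 1) * B;
        for (int i = 0; i < len; ++i) dp[i] += w * ds[i];
      }
    }
    return List::create(_["dx"] = dx, _["W"] = dW, _["b"] = db);
  }
  const int BLK = 8192;
  if (!need_dx) {
    for (int r0 = 0; r0 < M; r0 += BLK) {
      const int r1 = std::min(M, r0 + BLK);
      for (int j = 0; j < k; ++j) {
        const int dt = j - pl;
        const int lo = std::max(r0, std::max(0, -dt) * B);
        const int hi = std::min(r1, (std::min(T - 1, T - 1 - dt) + 1) * B);
        if (hi <= lo) continue;
        gemm('T', 'N', C, Cout, hi - lo, 1.0,
             x.begin() + (size_t)lo + (size_t)dt * B, M,
             dout.begin() + (size_t)lo, M,
             1.0, dW.begin() + j * C, kC);
      }
    }
    return List::create(_["dx"] = R_NilValue, _["W"] = dW, _["b"] = db);
  }
  NumericVector dx(Dimension(B, T, C));
  for (int r0 = 0; r0 < M; r0 += BLK) {
    const int r1 = std::min(M, r0 + BLK);
    for (int j = 0; j < k; ++j) {
      const int dt = j - pl;
      const int lo = std::max(r0, std::max(0, -dt) * B);
      const int hi = std::min(r1, (std::min(T - 1, T - 1 - dt) + 1) * B);
      if (hi <= lo) continue;
      // dW_j += t(X[rows+dt]) %*% dY[rows]
      gemm('T', 'N', C, Cout, hi - lo, 1.0,
           x.begin() + (size_t)lo + (size_t)dt * B, M,
           dout.begin() + (size_t)lo, M,
           1.0, dW.begin() + j * C, kC);
      // dX[rows+dt] += dY[rows] %*% t(W_j)
      gemm('N', 'T', hi - lo, C, Cout, 1.0,
           dout.begin() + (size_t)lo, M,
           W.begin() + j * C, kC,
           1.0, dx.begin() + (size_t)lo + (size_t)dt * B, M);
    }
  }
  return List::create(_["dx"] = dx, _["W"] = dW, _["b"] = db);
}

// [[Rcpp::export(name = ".bn_fw_train")]]
List bn_fw_train(NumericVector x, NumericVector gamma, NumericVector beta,
                 double eps, bool act) {
  IntegerVector d = dims3(x);
  const size_t M = (size_t)d[0] * d[1];
  const int C = d[2];
  NumericVector y(Dimension(d[0], d[1], C)), mu(C), inv(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + M * c;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < M; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / M;
    double v = s2 / M - m * m;
    if (v < 0) v = 0;
    const double iv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    double* yc = y.begin() + M * c;
    if (act) {
      for (size_t i = 0; i < M; ++i) {
        const double t = g * (xc[i] - m) * iv + b;
        yc[i] = t > 0 ? t : 0;
      }
    } else {
      for (size_t i = 0; i < M; ++i) yc[i] = g * (xc[i] - m) * iv + b;
    }
    mu[c] = m; var[c] = v; inv[c] = iv;
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var,
                      _["inv"] = inv);
}

// [[Rcpp::export(name = ".bn_fw_eval")]]
NumericVector bn_fw_eval(NumericVector x, NumericVector gamma,
                         NumericVector beta, NumericVector rmean,
                         NumericVector rvar, double eps, bool act) {
  IntegerVector d = dims3(x);
  const size_t M = (size_t)d[0] * d[1];
  const int C = d[2];
  NumericVector y(Dimension(d[0], d[1], C));
  for (int c = 0; c < C; ++c) {
    const double iv = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c], b = beta[c], m = rmean[c];
    const double* xc = x.begin() + M * c;
    double* yc = y.begin() + M * c;
    if (act) {
      for (size_t i = 0; i < M; ++i) {
        const double t = g * (xc[i] - m) * iv + b;
        yc[i] = t > 0 ? t : 0;
      }
    } else {
      for (size_t i = 0; i < M; ++i) yc[i] = g * (xc[i] - m) * iv + b;
    }
  }
  return y;
}

// backward through batch normalization, optionally preceded by the fused
// ReLU (y = activation output, used as the mask)
// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw(NumericVector x, NumericVector mu, NumericVector inv,
           NumericVector gamma, NumericVector dout,
           Nullable<NumericVector> y_act) {
  IntegerVector d = dims3(x);
  const size_t M = (size_t)d[0] * d[1];
  const int C = d[2];
  NumericVector dx(Dimension(d[0], d[1], C)), dgamma(C), dbeta(C);
  const double* yp = nullptr;
  if (y_act.isNotNull()) {
    NumericVector y(y_act);
    yp = y.begin();
  }
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + M * c;
    const double* dc = dout.begin() + M * c;
    const double* yc = yp ? yp + M * c : nullptr;
    const double m = mu[c], iv = inv[c], g = gamma[c];
    double sg = 0, sb = 0;
    for (size_t i = 0; i < M; ++i) {
      const double dv = yc ? (yc[i] > 0 ? dc[i] : 0.0) : dc[i];
      const double xh = (xc[i] - m) * iv;
      sg += dv * xh;
      sb += dv;
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double a1 = sb / M, a2 = sg / M, giv = g * iv;
    double* dd = dx.begin() + M * c;
    for (size_t i = 0; i < M; ++i) {
      const double dv = yc ? (yc[i] > 0 ? dc[i] : 0.0) : dc[i];
      const double xh = (xc[i] - m) * iv;
      dd[i] = giv * (dv - a1 - xh * a2);
    }
  }
  return List::create(_["dx"] = dx, _["gamma"] = dgamma, _["beta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fw")]]
NumericVector relu_fw(NumericVector x) {
  NumericVector y = clone(x);
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return y;
}

// [[Rcpp::export(name = ".relu_bw")]]
NumericVector relu_bw(NumericVector dout, NumericVector y) {
  NumericVector dx = clone(dout);
  dx.attr("dim") = dout.attr("dim");
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (y[i] <= 0) dx[i] = 0;
  return dx;
}

// [[Rcpp::export(name = ".pool_fw")]]
List pool_fw(NumericVector x, int p, bool use_max) {
  IntegerVector d = dims3(x);
  const int B = d[0], T = d[1], C = d[2];
  const int T2 = T / p;
  if (T2 < 1) stop("sequence too short for pooling width");
  NumericVector y(Dimension(B, T2, C));
  IntegerVector am(use_max ? (R_xlen_t)B * T2 * C : 0);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * B * T;
    double* yc = y.begin() + (size_t)c * B * T2;
    int* ac = use_max ? am.begin() + (size_t)c * B * T2 : nullptr;
    for (int t2 = 0; t2 < T2; ++t2) {
      for (int b = 0; b < B; ++b) {
        const size_t o = (size_t)t2 * p * B + b;
        if (use_max) {
          double m = xc[o]; int arg = 0;
          for (int j = 1; j < p; ++j) {
            const double v = xc[o + (size_t)j * B];
            if (v > m) { m = v; arg = j; }
          }
          yc[(size_t)t2 * B + b] = m;
          ac[(size_t)t2 * B + b] = arg;
        } else {
          double s = 0;
          for (int j = 0; j < p; ++j) s += xc[o + (size_t)j * B];
          yc[(size_t)t2 * B + b] = s / p;
        }
      }
    }
  }
  List out = List::create(_["y"] = y);
  if (use_max) { am.attr("dim") = Dimension(B, T2, C); out["am"] = am; }
  return out;
}

// [[Rcpp::export(name = ".pool_bw")]]
NumericVector pool_bw(NumericVector dout, Nullable<IntegerVector> am_, int p,
                      int T, bool use_max) {
  IntegerVector d = dims3(dout);
  const int B = d[0], T2 = d[1], C = d[2];
  NumericVector dx(Dimension(B, T, C));
  const int* am = nullptr;
  if (use_max) {
    IntegerVector a(am_);
    am = a.begin();
  }
  for (int c = 0; c < C; ++c) {
    const double* dc = dout.begin() + (size_t)c * B * T2;
    double* dd = dx.begin() + (size_t)c * B * T;
    const int* ac = use_max ? am + (size_t)c * B * T2 : nullptr;
    for (int t2 = 0; t2 < T2; ++t2) {
      for (int b = 0; b < B; ++b) {
        const double g = dc[(size_t)t2 * B + b];
        const size_t o = (size_t)t2 * p * B + b;
        if (use_max) {
          dd[o + (size_t)ac[(size_t)t2 * B + b] * B] += g;
        } else {
          const double gp = g / p;
          for (int j = 0; j < p; ++j) dd[o + (size_t)j * B] += gp;
        }
      }
    }
  }
  return dx;
}
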