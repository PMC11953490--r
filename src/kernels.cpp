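// Dense 2-D convolution / transposed-convolution / max-pool kernels for the
// segmentation network. Array layout everywhere: column-major (H, W, C, N),
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).
//
// Convolutions are stride-1 with "same" zero padding, implemented as
// im2col + GEMM. The im2col matrix is (H*W) x (k*k*C) so that both the
// forward product and the weight-gradient product are plain GEMMs.

#include <RcppArmadillo.h>
using namespace Rcpp;

// col: (H*W) x (k*k*C); column index = dy + k*dx + k*k*c.
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        double* cc = col.colptr(dy + k * dx + k * k * c);
        int i0 = std::max(0, pad - dy);
        int i1 = std::min(H, H + pad - dy);  // exclusive
        if (i1 <= i0) continue;
        for (int j = 0; j < W; ++j) {
          int sj = j + dx - pad;
          if (sj < 0 || sj >= W) continue;
          std::memcpy(cc + i0 + (size_t)H * j,
                      xc + (i0 + dy - pad) + (size_t)H * sj,
                      sizeof(double) * (i1 - i0));
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& col, double* dx, int H, int W, int C,
                   int k, int pad) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int dx_ = 0; dx_ < k; ++dx_) {
      for (int dy = 0; dy < k; ++dy) {
        const double* cc = col.colptr(dy + k * dx_ + k * k * c);
        int i0 = std::max(0, pad - dy);
        int i1 = std::min(H, H + pad - dy);
        if (i1 <= i0) continue;
        for (int j = 0; j < W; ++j) {
          int sj = j + dx_ - pad;
          if (sj < 0 || sj >= W) continue;
          const double* src = cc + i0 + (size_t)H * j;
          double* dst = xc + (i0 + dy - pad) + (size_t)H * sj;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3], pad = (k - 1) / 2;
  size_t HW = (size_t)H * W, kkC = (size_t)k * k * C;
  NumericVector y((R_xlen_t)(HW * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), kkC, Cout, false);
  arma::mat col(HW, kkC);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + HW * C * n, H, W, C, k, pad, col);
    arma::mat ym(y.begin() + HW * Cout * n, HW, Cout, false, true);
    ym = col * Wm;
    for (int co = 0; co < Cout; ++co) ym.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3], pad = (k - 1) / 2;
  size_t HW = (size_t)H * W, kkC = (size_t)k * k * C;
  NumericVector dx((R_xlen_t)x.size()), dw((R_xlen_t)w.size()),
      db((R_xlen_t)Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat Wm(w.begin(), kkC, Cout, false);
  arma::mat dWm(dw.begin(), kkC, Cout, false, true);
  arma::mat col(HW, kkC), dcol(HW, kkC);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + HW * C * n, H, W, C, k, pad, col);
    arma::mat dym(dy.begin() + HW * Cout * n, HW, Cout, false);
    dWm += col.t() * dym;
    dcol = dym * Wm.t();
    col2im(dcol, dx.begin() + HW * C * n, H, W, C, k, pad);
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dym.col(co));
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// Transposed conv, 2x2 kernel, stride 2: (H, W, Cin, N) -> (2H, 2W, Cout, N).
// Weight layout (2, 2, Cin, Cout):
//   y[2i+dy, 2j+dx, co] = sum_ci w[dy, dx, ci, co] * x[i, j, ci] + b[co]

// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  int H2 = 2 * H, W2 = 2 * W;
  size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  NumericVector y((R_xlen_t)(HW2 * Cout * N));
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  arma::mat Ys(HW, Cout);
  for (int dy = 0; dy < 2; ++dy) {
    for (int dx = 0; dx < 2; ++dx) {
      arma::mat Wsub(Cin, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wsub(ci, co) = w[dy + 2 * dx + 4 * ci + (size_t)4 * Cin * co];
      for (int n = 0; n < N; ++n) {
        arma::mat Xm(x.begin() + HW * Cin * n, HW, Cin, false);
        Ys = Xm * Wsub;
        double* yn = y.begin() + HW2 * Cout * n;
        for (int co = 0; co < Cout; ++co) {
          double* yc = yn + HW2 * co;
          const double* sc = Ys.colptr(co);
          double bc = b[co];
          for (int j = 0; j < W; ++j) {
            double* ycol = yc + dy + (size_t)H2 * (2 * j + dx);
            const double* scol = sc + (size_t)H * j;
            for (int i = 0; i < H; ++i) ycol[2 * i] = scol[i] + bc;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  int H2 = 2 * H, W2 = 2 * W;
  size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  NumericVector dx((R_xlen_t)x.size()), dw((R_xlen_t)w.size()),
      db((R_xlen_t)Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat dYs(HW, Cout);
  for (int dy_ = 0; dy_ < 2; ++dy_) {
    for (int dx_ = 0; dx_ < 2; ++dx_) {
      arma::mat Wsub(Cin, Cout), dWsub(Cin, Cout, arma::fill::zeros);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wsub(ci, co) = w[dy_ + 2 * dx_ + 4 * ci + (size_t)4 * Cin * co];
      for (int n = 0; n < N; ++n) {
        const double* gn = dy.begin() + HW2 * Cout * n;
        for (int co = 0; co < Cout; ++co) {
          const double* gc = gn + HW2 * co;
          double* dc = dYs.colptr(co);
          for (int j = 0; j < W; ++j) {
            const double* gcol = gc + dy_ + (size_t)H2 * (2 * j + dx_);
            double* dcol = dc + (size_t)H * j;
            for (int i = 0; i < H; ++i) dcol[i] = gcol[2 * i];
          }
        }
        arma::mat Xm(x.begin() + HW * Cin * n, HW, Cin, false);
        arma::mat dXm(dx.begin() + HW * Cin * n, HW, Cin, false, true);
        dWsub += Xm.t() * dYs;
        dXm += dYs * Wsub.t();
      }
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          dw[dy_ + 2 * dx_ + 4 * ci + (size_t)4 * Cin * co] = dWsub(ci, co);
    }
  }
  for (int n = 0; n < N; ++n) {
    const double* gn = dy.begin() + HW2 * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gn + HW2 * co;
      double s = 0.0;
      for (size_t t = 0; t < HW2; ++t) s += gc[t];
      db[co] += s;
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based linear
// indices (into the input vector) of each maximum, for the backward pass.

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  size_t HWo = (size_t)Ho * Wo;
  NumericVector y((R_xlen_t)(HWo * C * N));
  IntegerVector idx((R_xlen_t)(HWo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  size_t plane = (size_t)H * W;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = xp + plane * cn;
    size_t base = plane * cn;
    double* yc = y.begin() + HWo * cn;
    int* ic = idx.begin() + HWo * cn;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        size_t p00 = (size_t)2 * io + (size_t)H * (2 * jo);
        size_t cand[4] = {p00, p00 + 1, p00 + (size_t)H, p00 + (size_t)H + 1};
        int best = 0;
        double bv = xc[cand[0]];
        for (int t = 1; t < 4; ++t)
          if (xc[cand[t]] > bv) {
            bv = xc[cand[t]];
            best = t;
          }
        yc[io + (size_t)Ho * jo] = bv;
        ic[io + (size_t)Ho * jo] = (int)(base + cand[best] + 1);
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx((R_xlen_t)n);
  dx.attr("dim") = xdim;
  double* dp = dx.begin();
  for (R_xlen_t t = 0; t < dy.size(); ++t) dp[idx[t] - 1] += dy[t];
  return dx;
}

// Instance normalization over spatial dims, one (channel, sample) group per
// column of the (H*W) x (C*N) view. Returns y, xhat and the per-group
// inverse standard deviation needed by the backward pass.

// [[Rcpp::export]]
List cpp_instnorm_fwd(NumericVector x, NumericVector gamma,
                      NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t m = (size_t)H * W;
  int G = C * N;
  NumericVector y((R_xlen_t)x.size()), xhat((R_xlen_t)x.size()),
      invstd((R_xlen_t)G);
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int g = 0; g < G; ++g) {
    const double* xc = xp + m * g;
    double* yc = yp + m * g;
    double* hc = hp + m * g;
    double mu = 0.0, v = 0.0;
    for (size_t i = 0; i < m; ++i) mu += xc[i];
    mu /= m;
    for (size_t i = 0; i < m; ++i) {
      double d = xc[i] - mu;
      v += d * d;
    }
    v /= m;
    double is = 1.0 / std::sqrt(v + eps);
    invstd[g] = is;
    double ga = gamma[g % C], be = beta[g % C];
    for (size_t i = 0; i < m; ++i) {
      hc[i] = (xc[i] - mu) * is;
      yc[i] = ga * hc[i] + be;
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("invstd") = invstd);
}

// [[Rcpp::export]]
List cpp_instnorm_bwd(NumericVector dy, NumericVector xhat,
                      NumericVector invstd, NumericVector gamma,
                      IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t m = (size_t)H * W;
  int G = C * N;
  NumericVector dx((R_xlen_t)dy.size()), dgamma((R_xlen_t)C),
      dbeta((R_xlen_t)C);
  dx.attr("dim") = xdim;
  const double* gp = dy.begin();
  const double* hp = xhat.begin();
  double* dp = dx.begin();
  for (int g = 0; g < G; ++g) {
    const double* gc = gp + m * g;
    const double* hc = hp + m * g;
    double* dc = dp + m * g;
    double ga = gamma[g % C];
    double s1 = 0.0, s2 = 0.0, dg = 0.0, db = 0.0;
    for (size_t i = 0; i < m; ++i) {
      dg += gc[i] * hc[i];
      db += gc[i];
    }
    dgamma[g % C] += dg;
    dbeta[g % C] += db;
    s1 = db * ga / m;
    s2 = dg * ga / m;
    double is = invstd[g];
    for (size_t i = 0; i < m; ++i) {
      dc[i] = is * (ga * gc[i] - s1 - hc[i] * s2);
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// dy * (y > 0)
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx((R_xlen_t)dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* gp = dy.begin();
  const double* yp = y.begin();
  double* dp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dp[i] = yp[i] > 0 ? gp[i] : 0.0;
  return dx;
}
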