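// Low-level convolution and pooling kernels for the CPU network engine.
// Tensors are R arrays in (H, W, C, N) layout (column-major, H fastest);
// convolution weights are (kh, kw, Cin/groups, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int dims[4]) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) dims[i] = d[i];
}

// Gather one (group, image) patch matrix: cols is (kh*kw*cin_g) x (Ho*Wo).
static void im2col(const double *x, int H, int W, int C, int n,
                   int g, int cin_g, int kh, int kw,
                   int stride, int pad, int Ho, int Wo, arma::mat &cols) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      double *dst = cols.colptr(p);
      for (int ci = 0; ci < cin_g; ++ci) {
        const int c = g * cin_g + ci;
        const double *xc = x + (size_t)H * W * (c + (size_t)C * n);
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * stride - pad + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * stride - pad + ki;
            const int r = ki + kh * (kj + kw * ci);
            dst[r] = (hi >= 0 && hi < H && wi >= 0 && wi < W)
                         ? xc[hi + (size_t)H * wi]
                         : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(double *dx, int H, int W, int C, int n,
                       int g, int cin_g, int kh, int kw,
                       int stride, int pad, int Ho, int Wo,
                       const arma::mat &dcols) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      const double *src = dcols.colptr(p);
      for (int ci = 0; ci < cin_g; ++ci) {
        const int c = g * cin_g + ci;
        double *xc = dx + (size_t)H * W * (c + (size_t)C * n);
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            const int r = ki + kh * (kj + kw * ci);
            xc[hi + (size_t)H * wi] += src[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 Nullable<NumericVector> bias,
                                 int stride, int pad, int groups) {
  int xd[4], wd[4];
  get_dims4(x, xd);
  get_dims4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cin_g = wd[2], cout = wd[3];
  if (C != cin_g * groups) stop("input channels inconsistent with groups");
  if (cout % groups != 0) stop("output channels not divisible by groups");
  const int cout_g = cout / groups;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  NumericVector y((size_t)Ho * Wo * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);

  const int K = kh * kw * cin_g;
  arma::mat cols(K, (size_t)Ho * Wo);
  const arma::mat Wm(const_cast<double *>(w.begin()), K, cout, false, true);
  const double *bptr = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) {
    bv = bias.get();
    if ((int)bv.size() != cout) stop("bias length must equal Cout");
    bptr = bv.begin();
  }

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, C, n, g, cin_g, kh, kw, stride, pad, Ho, Wo,
             cols);
      arma::mat Yg(y.begin() + (size_t)Ho * Wo * (g * cout_g + (size_t)cout * n),
                   (size_t)Ho * Wo, cout_g, false, true);
      Yg = cols.t() * Wm.cols(g * cout_g, (g + 1) * cout_g - 1);
      if (bptr) {
        for (int o = 0; o < cout_g; ++o)
          Yg.col(o) += bptr[g * cout_g + o];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad, int groups, bool need_dx,
                         bool has_bias) {
  int xd[4], wd[4], yd[4];
  get_dims4(x, xd);
  get_dims4(w, wd);
  get_dims4(dy, yd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cin_g = wd[2], cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int cout_g = cout / groups;
  const int K = kh * kw * cin_g;

  NumericVector dw((size_t)kh * kw * cin_g * cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, cin_g, cout);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  NumericVector db(has_bias ? cout : 0);

  arma::mat cols(K, (size_t)Ho * Wo);
  arma::mat dWm(dw.begin(), K, cout, false, true);
  const arma::mat Wm(const_cast<double *>(w.begin()), K, cout, false, true);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const arma::mat dYg(
          const_cast<double *>(dy.begin()) +
              (size_t)Ho * Wo * (g * cout_g + (size_t)cout * n),
          (size_t)Ho * Wo, cout_g, false, true);
      im2col(x.begin(), H, W, C, n, g, cin_g, kh, kw, stride, pad, Ho, Wo,
             cols);
      dWm.cols(g * cout_g, (g + 1) * cout_g - 1) += cols * dYg;
      if (has_bias) {
        for (int o = 0; o < cout_g; ++o)
          db[g * cout_g + o] += arma::accu(dYg.col(o));
      }
      if (need_dx) {
        arma::mat dcols =
            Wm.cols(g * cout_g, (g + 1) * cout_g - 1) * dYg.t();
        col2im_add(dx.begin(), H, W, C, n, g, cin_g, kh, kw, stride, pad, Ho,
                   Wo, dcols);
      }
    }
  }
  List out = List::create(Named("dw") = dw);
  if (need_dx) out["dx"] = dx;
  if (has_bias) out["db"] = db;
  return out;
}

// 2x2 max pooling with stride 2 (pads nothing; even dims enforced in R).
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  int xd[4];
  get_dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // linear index into x, 0-based

  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t i00 = base + (size_t)(2 * ho) + (size_t)H * (2 * wo);
          size_t best = i00;
          double v = xp[i00];
          const size_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > v) { v = xp[cand[k]]; best = cand[k]; }
          yp[o] = v;
          ip[o] = (int)best;
          ++o;
        }
      }
    }
  }
  // iterate matched (ho fastest, then wo, c, n) == output memory order? Output
  // layout is (Ho, Wo, C, N): offset ho + Ho*(wo + Wo*(c + C*n)). The loop
  // above fills o in order n, c, wo, ho which matches that layout.
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    IntegerVector in_dim) {
  NumericVector dx((size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  const double *dyp = dy.begin();
  const int *ip = idx.begin();
  double *dxp = dx.begin();
  const size_t m = dy.size();
  for (size_t o = 0; o < m; ++o) dxp[ip[o]] += dyp[o];
  return dx;
}

// Forward pass that also returns the im2col patch matrix for reuse in the
// backward pass (ungrouped convolutions only).
// [[Rcpp::export]]
List cpp_conv2d_forward_train(NumericVector x, NumericVector w,
                              Nullable<NumericVector> bias,
                              int stride, int pad) {
  int xd[4], wd[4];
  get_dims4(x, xd);
  get_dims4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cin_g = wd[2], cout = wd[3];
  if (C != cin_g) stop("grouped convolutions use the ungrouped path");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * cin_g;

  NumericVector y((size_t)Ho * Wo * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  NumericVector cols_out((size_t)K * Ho * Wo * N);
  cols_out.attr("dim") = IntegerVector::create(K, Ho * Wo * N);

  const arma::mat Wm(const_cast<double *>(w.begin()), K, cout, false, true);
  const double *bptr = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) {
    bv = bias.get();
    bptr = bv.begin();
  }
  for (int n = 0; n < N; ++n) {
    arma::mat cols(cols_out.begin() + (size_t)K * Ho * Wo * n, K,
                   (size_t)Ho * Wo, false, true);
    im2col(x.begin(), H, W, C, n, 0, cin_g, kh, kw, stride, pad, Ho, Wo,
           cols);
    arma::mat Yg(y.begin() + (size_t)Ho * Wo * cout * n, (size_t)Ho * Wo,
                 cout, false, true);
    Yg = cols.t() * Wm;
    if (bptr)
      for (int o = 0; o < cout; ++o) Yg.col(o) += bptr[o];
  }
  return List::create(Named("y") = y, Named("cols") = cols_out);
}

// Backward pass reusing the cached patch matrix (ungrouped only).
// [[Rcpp::export]]
List cpp_conv2d_backward_cols(NumericVector cols_in, IntegerVector x_dim,
                              NumericVector w, NumericVector dy,
                              int stride, int pad, bool need_dx,
                              bool has_bias) {
  int wd[4], yd[4];
  get_dims4(w, wd);
  get_dims4(dy, yd);
  const int H = x_dim[0], W = x_dim[1], C = x_dim[2], N = x_dim[3];
  const int kh = wd[0], kw = wd[1], cin_g = wd[2], cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * cin_g;

  NumericVector dw((size_t)kh * kw * cin_g * cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, cin_g, cout);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  NumericVector db(has_bias ? cout : 0);
  arma::mat dWm(dw.begin(), K, cout, false, true);
  const arma::mat Wm(const_cast<double *>(w.begin()), K, cout, false, true);

  for (int n = 0; n < N; ++n) {
    const arma::mat cols(const_cast<double *>(cols_in.begin()) +
                             (size_t)K * Ho * Wo * n,
                         K, (size_t)Ho * Wo, false, true);
    const arma::mat dYg(const_cast<double *>(dy.begin()) +
                            (size_t)Ho * Wo * cout * n,
                        (size_t)Ho * Wo, cout, false, true);
    dWm += cols * dYg;
    if (has_bias)
      for (int o = 0; o < cout; ++o) db[o] += arma::accu(dYg.col(o));
    if (need_dx) {
      arma::mat dcols = Wm * dYg.t();
      col2im_add(dx.begin(), H, W, C, n, 0, cin_g, kh, kw, stride, pad, Ho,
                 Wo, dcols);
    }
  }
  List out = List::create(Named("dw") = dw);
  if (need_dx) out["dx"] = dx;
  if (has_bias) out["db"] = db;
  return out;
}

// Fused batch-norm training forward: per-channel batch statistics and the
// normalised/scaled output in one pass.
// [[Rcpp::export]]
List cpp_bn_forward_train(NumericVector x, NumericVector gamma,
                          NumericVector beta, double eps) {
  int xd[4];
  get_dims4(x, xd);
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double cnt = (double)hw * N;
  NumericVector mu(C), var(C);
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = xp + hw * (c + (size_t)C * n);
      double s = 0, s2 = 0;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mu[c] += s; var[c] += s2;
    }
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) {
    mu[c] /= cnt;
    var[c] = var[c] / cnt - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
    istd[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = gamma[c] * istd[c];
      const double b = beta[c] - mu[c] * a;
      const double *p = xp + hw * (c + (size_t)C * n);
      double *q = yp + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) q[i] = a * p[i] + b;
    }
  return List::create(Named("y") = y, Named("mu") = mu, Named("var") = var,
                      Named("istd") = istd);
}

// Fused batch-norm backward from the cached statistics.
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector x, NumericVector dy, NumericVector gamma,
                     NumericVector mu, NumericVector istd, bool need_dx) {
  int xd[4];
  get_dims4(x, xd);
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double cnt = (double)hw * N;
  NumericVector dgamma(C), dbeta(C);
  const double *xp = x.begin();
  const double *dp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *px = xp + hw * (c + (size_t)C * n);
      const double *pd = dp + hw * (c + (size_t)C * n);
      double sg = 0, sb = 0;
      for (size_t i = 0; i < hw; ++i) {
        sg += pd[i] * (px[i] - mu[c]) * istd[c];
        sb += pd[i];
      }
      dgamma[c] += sg; dbeta[c] += sb;
    }
  List out = List::create(Named("dgamma") = dgamma, Named("dbeta") = dbeta);
  if (need_dx) {
    NumericVector dx(x.size());
    dx.attr("dim") = x.attr("dim");
    double *q = dx.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double a = gamma[c] * istd[c] / cnt;
        const double *px = xp + hw * (c + (size_t)C * n);
        const double *pd = dp + hw * (c + (size_t)C * n);
        double *pq = q + hw * (c + (size_t)C * n);
        for (size_t i = 0; i < hw; ++i) {
          const double xhat = (px[i] - mu[c]) * istd[c];
          pq[i] = a * (cnt * pd[i] - dbeta[c] - xhat * dgamma[c]);
        }
      }
    out["dx"] = dx;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *p = x.begin();
  double *q = y.begin();
  const size_t m = x.size();
  for (size_t i = 0; i < m; ++i) q[i] = p[i] > 0 ? p[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  const double *p = x.begin();
  const double *d = dy.begin();
  double *q = dx.begin();
  const size_t m = x.size();
  for (size_t i = 0; i < m; ++i) q[i] = p[i] > 0 ? d[i] : 0;
  return dx;
}
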