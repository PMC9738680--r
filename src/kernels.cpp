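// Hot numerical kernels for the neural-network core.
//
// Activations use the layout (H, W, N, C), column-major as stored by R.
// Convolutions run as im2col + one BLAS product; backward recomputes the
// patch matrix and scatters with col2im. All kernels are exercised against
// finite-difference oracles in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::ivec get_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return arma::conv_to<arma::ivec>::from(as<arma::ivec>(d));
}

// gather the padded input into an (Ho*Wo*N) x (kh*kw*C) patch matrix
static arma::mat im2col(const double* x, int H, int W, int N, int C,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  const arma::uword M = (arma::uword)Ho * Wo * N;
  arma::mat col(M, (arma::uword)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        double* dst = col.colptr((arma::uword)(di + kh * dj) + (arma::uword)kh * kw * c);
        for (int n = 0; n < N; ++n) {
          for (int jo = 0; jo < Wo; ++jo) {
            int j = jo * stride + dj - pad;              // source column
            arma::uword base = (arma::uword)Ho * (jo + (arma::uword)Wo * n);
            if (j < 0 || j >= W) continue;
            const double* src = x + (arma::uword)H * (j + (arma::uword)W * (n + (arma::uword)N * c));
            for (int io = 0; io < Ho; ++io) {
              int i = io * stride + di - pad;
              if (i < 0 || i >= H) continue;
              dst[base + io] = src[i];
            }
          }
        }
      }
    }
  }
  return col;
}

// scatter-add a patch-matrix gradient back onto the input
static void col2im(const arma::mat& dcol, double* dx, int H, int W, int N,
                   int C, int kh, int kw, int stride, int pad,
                   int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const double* src = dcol.colptr((arma::uword)(di + kh * dj) + (arma::uword)kh * kw * c);
        for (int n = 0; n < N; ++n) {
          for (int jo = 0; jo < Wo; ++jo) {
            int j = jo * stride + dj - pad;
            if (j < 0 || j >= W) continue;
            arma::uword base = (arma::uword)Ho * (jo + (arma::uword)Wo * n);
            double* dst = dx + (arma::uword)H * (j + (arma::uword)W * (n + (arma::uword)N * c));
            for (int io = 0; io < Ho; ++io) {
              int i = io * stride + di - pad;
              if (i < 0 || i >= H) continue;
              dst[i] += src[base + io];
            }
          }
        }
      }
    }
  }
}

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector W, NumericVector b,
                        int stride, int pad) {
  arma::ivec dx = get_dims(x), dw = get_dims(W);
  int H = dx[0], Wd = dx[1], N = dx[2], C = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(Wd, kw, stride, pad);
  arma::mat col = im2col(x.begin(), H, Wd, N, C, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(W.begin(), (arma::uword)kh * kw * C, Cout, false, true);
  arma::mat y = col * Wm;
  y.each_row() += arma::rowvec(b.begin(), Cout, false, true);
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector W, NumericVector dy,
               int stride, int pad) {
  arma::ivec dxd = get_dims(x), dwd = get_dims(W);
  int H = dxd[0], Wd = dxd[1], N = dxd[2], C = dxd[3];
  int kh = dwd[0], kw = dwd[1], Cout = dwd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(Wd, kw, stride, pad);
  arma::uword M = (arma::uword)Ho * Wo * N;
  arma::mat col = im2col(x.begin(), H, Wd, N, C, kh, kw, stride, pad, Ho, Wo);
  arma::mat dym(dy.begin(), M, Cout, false, true);
  arma::mat Wm(W.begin(), (arma::uword)kh * kw * C, Cout, false, true);
  arma::mat dW = col.t() * dym;
  arma::rowvec db = arma::sum(dym, 0);
  arma::mat dcol = dym * Wm.t();
  NumericVector dxv((arma::uword)H * Wd * N * C);
  col2im(dcol, dxv.begin(), H, Wd, N, C, kh, kw, stride, pad, Ho, Wo);
  dxv.attr("dim") = IntegerVector::create(H, Wd, N, C);
  NumericVector dWv(dW.begin(), dW.end());
  dWv.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  return List::create(_["dx"] = dxv, _["dW"] = dWv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".dwconv2d_fw")]]
NumericVector dwconv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  arma::ivec dx = get_dims(x), dw = get_dims(w);
  int H = dx[0], Wd = dx[1], N = dx[2], C = dx[3];
  int kh = dw[0], kw = dw[1];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(Wd, kw, stride, pad);
  NumericVector out((arma::uword)Ho * Wo * N * C);
  const double* xp = x.begin();
  double* yp = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* plane = xp + (arma::uword)H * Wd * (n + (arma::uword)N * c);
      double* oplane = yp + (arma::uword)Ho * Wo * (n + (arma::uword)N * c);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double acc = b[c];
          for (int dj = 0; dj < kw; ++dj) {
            int j = jo * stride + dj - pad;
            if (j < 0 || j >= Wd) continue;
            for (int di = 0; di < kh; ++di) {
              int i = io * stride + di - pad;
              if (i < 0 || i >= H) continue;
              acc += plane[i + (arma::uword)H * j] * w[di + kh * (dj + kw * c)];
            }
          }
          oplane[io + (arma::uword)Ho * jo] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return out;
}

// [[Rcpp::export(name = ".dwconv2d_bw")]]
List dwconv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad) {
  arma::ivec dxd = get_dims(x), dwd = get_dims(w);
  int H = dxd[0], Wd = dxd[1], N = dxd[2], C = dxd[3];
  int kh = dwd[0], kw = dwd[1];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(Wd, kw, stride, pad);
  NumericVector dxv((arma::uword)H * Wd * N * C);
  NumericVector dwv((arma::uword)kh * kw * C);
  NumericVector dbv(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dxv.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* plane = xp + (arma::uword)H * Wd * (n + (arma::uword)N * c);
      double* dplane = dxp + (arma::uword)H * Wd * (n + (arma::uword)N * c);
      const double* gplane = dyp + (arma::uword)Ho * Wo * (n + (arma::uword)N * c);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double g = gplane[io + (arma::uword)Ho * jo];
          dbv[c] += g;
          for (int dj = 0; dj < kw; ++dj) {
            int j = jo * stride + dj - pad;
            if (j < 0 || j >= Wd) continue;
            for (int di = 0; di < kh; ++di) {
              int i = io * stride + di - pad;
              if (i < 0 || i >= H) continue;
              dwv[di + kh * (dj + kw * c)] += plane[i + (arma::uword)H * j] * g;
              dplane[i + (arma::uword)H * j] += w[di + kh * (dj + kw * c)] * g;
            }
          }
        }
      }
    }
  }
  dxv.attr("dim") = IntegerVector::create(H, Wd, N, C);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C);
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// batch normalization; x is any array whose last dimension is C (treated as
// an (M x C) matrix without copying). When training, batch moments are
// computed here and returned.
// [[Rcpp::export(name = ".bn_fw")]]
List bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
           NumericVector mu_in, NumericVector va_in, double eps,
           bool training) {
  int C = gamma.size();
  arma::uword M = x.size() / C;
  NumericVector y(x.size()), xhat(x.size());
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + M * c;
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (arma::uword i = 0; i < M; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
    } else {
      m = mu_in[c]; v = va_in[c];
    }
    mu[c] = m; va[c] = v;
    double istd = 1.0 / std::sqrt(v + eps);
    double g = gamma[c], be = beta[c];
    double* yc = y.begin() + M * c;
    double* hc = xhat.begin() + M * c;
    for (arma::uword i = 0; i < M; ++i) {
      double h = (xc[i] - m) * istd;
      hc[i] = h;
      yc[i] = h * g + be;
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw(NumericVector dy, NumericVector xhat, NumericVector gamma,
           NumericVector istd, bool training) {
  int C = gamma.size();
  arma::uword M = dy.size() / C;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dc = dy.begin() + M * c;
    const double* hc = xhat.begin() + M * c;
    double* ox = dx.begin() + M * c;
    double g = gamma[c];
    double sg = 0, sb = 0;
    for (arma::uword i = 0; i < M; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    if (training) {
      double m1 = g * sb / M;
      double m2 = g * sg / M;
      for (arma::uword i = 0; i < M; ++i)
        ox[i] = (dc[i] * g - m1 - hc[i] * m2) * istd[c];
    } else {
      for (arma::uword i = 0; i < M; ++i)
        ox[i] = dc[i] * g * istd[c];
    }
  }
  dx.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 2x2 average pooling, stride 2 (even H, W) on (H, W, N, C)
// [[Rcpp::export(name = ".avgpool2_fw")]]
NumericVector avgpool2_fw(NumericVector x) {
  arma::ivec d = get_dims(x);
  int H = d[0], W = d[1];
  arma::uword P = (arma::uword)d[2] * d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((arma::uword)Ho * Wo * P);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (arma::uword p = 0; p < P; ++p) {
    const double* pl = xp + (arma::uword)H * W * p;
    double* op = yp + (arma::uword)Ho * Wo * p;
    for (int j = 0; j < Wo; ++j) {
      const double* c0 = pl + (arma::uword)H * 2 * j;
      const double* c1 = c0 + H;
      for (int i = 0; i < Ho; ++i)
        op[i + (arma::uword)Ho * j] =
          0.25 * (c0[2 * i] + c0[2 * i + 1] + c1[2 * i] + c1[2 * i + 1]);
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, d[2], d[3]);
  return y;
}

// [[Rcpp::export(name = ".avgpool2_bw")]]
NumericVector avgpool2_bw(NumericVector dy, int H, int W) {
  arma::ivec d = get_dims(dy);
  int Ho = d[0], Wo = d[1];
  arma::uword P = (arma::uword)d[2] * d[3];
  NumericVector dx((arma::uword)H * W * P);
  const double* gp = dy.begin();
  double* xp = dx.begin();
  for (arma::uword p = 0; p < P; ++p) {
    const double* ip = gp + (arma::uword)Ho * Wo * p;
    double* pl = xp + (arma::uword)H * W * p;
    for (int j = 0; j < Wo; ++j) {
      double* c0 = pl + (arma::uword)H * 2 * j;
      double* c1 = c0 + H;
      for (int i = 0; i < Ho; ++i) {
        double g = 0.25 * ip[i + (arma::uword)Ho * j];
        c0[2 * i] = g; c0[2 * i + 1] = g; c1[2 * i] = g; c1[2 * i + 1] = g;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, d[2], d[3]);
  return dx;
}
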