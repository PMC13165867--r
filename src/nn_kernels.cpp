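// Dense CNN primitives on (H, W, C, N) column-major arrays.
// Convolutions go through im2col + BLAS gemm; transposed convolution is the
// backward-data pass of a virtual forward convolution (col2im of a gemm).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int dil, int pad) {
  int eff = (k - 1) * dil + 1;
  return (in + pad - eff) / stride + 1;
}

// Fill col (K x Ho*Wo) for sample n. K rows indexed r = dh + kh*(dw + kw*ci),
// matching the memory order of a (kh, kw, Cin, Cout) weight array.
static void im2col_sample(const double* x, int H, int W, int C,
                          int kh, int kw, int sh, int sw, int dil,
                          int pt, int pl, int Ho, int Wo, arma::mat& col) {
  const int plane = H * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int q = ho + Ho * wo;
      double* cq = col.colptr(q);
      for (int ci = 0; ci < C; ++ci) {
        const double* xp = x + (size_t)plane * ci;
        for (int dw = 0; dw < kw; ++dw) {
          int iw = wo * sw - pl + dw * dil;
          bool wok = (iw >= 0 && iw < W);
          for (int dh = 0; dh < kh; ++dh) {
            int ih = ho * sh - pt + dh * dil;
            double v = 0.0;
            if (wok && ih >= 0 && ih < H) v = xp[ih + H * iw];
            cq[dh + kh * (dw + kw * ci)] = v;
          }
        }
      }
    }
  }
}

// Scatter-add col (K x Ho*Wo) back into image gx for sample n (inverse of im2col).
static void col2im_sample(const arma::mat& col, double* gx, int H, int W, int C,
                          int kh, int kw, int sh, int sw, int dil,
                          int pt, int pl, int Ho, int Wo) {
  const int plane = H * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int q = ho + Ho * wo;
      const double* cq = col.colptr(q);
      for (int ci = 0; ci < C; ++ci) {
        double* xp = gx + (size_t)plane * ci;
        for (int dw = 0; dw < kw; ++dw) {
          int iw = wo * sw - pl + dw * dil;
          if (iw < 0 || iw >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int ih = ho * sh - pt + dh * dil;
            if (ih < 0 || ih >= H) continue;
            xp[ih + H * iw] += cq[dh + kh * (dw + kw * ci)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int sh, int sw, int dil, int pt, int pl,
                          int Ho, int Wo) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int K = kh * kw * C, M = Ho * Wo;
  NumericVector y(Ho * (R_xlen_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, M);
  bool has_b = b.size() == Cout;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    im2col_sample(xn, H, W, C, kh, kw, sh, sw, dil, pt, pl, Ho, Wo, col);
    arma::mat out = wm.t() * col;  // Cout x M
    double* yn = y.begin() + (size_t)M * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double bb = has_b ? b[co] : 0.0;
      double* yp = yn + (size_t)M * co;
      for (int q = 0; q < M; ++q) yp[q] = out(co, q) + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                 int sh, int sw, int dil, int pt, int pl, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  int K = kh * kw * C, M = Ho * Wo;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);
  arma::mat wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gwm(gw.begin(), K, Cout, false, true);
  arma::mat col(K, M), gym(Cout, M);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    const double* gyn = gy.begin() + (size_t)M * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (int q = 0; q < M; ++q) gym(co, q) = gyn[q + (size_t)M * co];
    im2col_sample(xn, H, W, C, kh, kw, sh, sw, dil, pt, pl, Ho, Wo, col);
    gwm += col * gym.t();
    arma::mat gcol = wm * gym;  // K x M
    col2im_sample(gcol, gx.begin() + (size_t)H * W * C * n,
                  H, W, C, kh, kw, sh, sw, dil, pt, pl, Ho, Wo);
    if (has_bias)
      for (int co = 0; co < Cout; ++co)
        gb[co] += arma::accu(gym.row(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, weights (kh, kw, Cout, Cin): backward-data of the
// virtual convolution that maps the (Ho,Wo,Cout) output down to the input grid.
// [[Rcpp::export]]
NumericVector nn_convt_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pt, int pl, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int Hi = xd[0], Wi = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[2];
  int K = kh * kw * Cout, M = Hi * Wi;
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  arma::mat xm(Cin, M);
  bool has_b = b.size() == Cout;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)M * Cin * n;
    for (int ci = 0; ci < Cin; ++ci)
      for (int q = 0; q < M; ++q) xm(ci, q) = xn[q + (size_t)M * ci];
    arma::mat col = wm * xm;  // K x M
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    col2im_sample(col, yn, Ho, Wo, Cout, kh, kw, stride, stride, 1,
                  pt, pl, Hi, Wi);
    if (has_b) {
      int plane = Ho * Wo;
      for (int co = 0; co < Cout; ++co) {
        double* yp = yn + (size_t)plane * co;
        for (int q = 0; q < plane; ++q) yp[q] += b[co];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_convt_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pt, int pl) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int Hi = xd[0], Wi = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[2];
  int Ho = gd[0], Wo = gd[1];
  int K = kh * kw * Cout, M = Hi * Wi;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  arma::mat gwm(gw.begin(), K, Cin, false, true);
  arma::mat gcol(K, M), xm(Cin, M);
  for (int n = 0; n < N; ++n) {
    const double* gyn = gy.begin() + (size_t)Ho * Wo * Cout * n;
    const double* xn = x.begin() + (size_t)M * Cin * n;
    im2col_sample(gyn, Ho, Wo, Cout, kh, kw, stride, stride, 1,
                  pt, pl, Hi, Wi, gcol);
    for (int ci = 0; ci < Cin; ++ci)
      for (int q = 0; q < M; ++q) xm(ci, q) = xn[q + (size_t)M * ci];
    arma::mat gxm = wm.t() * gcol;  // Cin x M
    double* gxn = gx.begin() + (size_t)M * Cin * n;
    for (int ci = 0; ci < Cin; ++ci)
      for (int q = 0; q < M; ++q) gxn[q + (size_t)M * ci] = gxm(ci, q);
    gwm += gcol * xm.t();
    int plane = Ho * Wo;
    for (int co = 0; co < Cout; ++co) {
      const double* gp = gyn + (size_t)plane * co;
      double s = 0.0;
      for (int q = 0; q < plane; ++q) s += gp[q];
      gb[co] += s;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x, int kh, int kw, int sh, int sw,
                    int pt, int pl, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  R_xlen_t ylen = (R_xlen_t)Ho * Wo * C * N;
  NumericVector y(ylen);
  IntegerVector am(ylen);  // argmax as h + H*w within the channel plane
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* ap = am.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int bi = -1;
          for (int dw = 0; dw < kw; ++dw) {
            int iw = wo * sw - pl + dw;
            if (iw < 0 || iw >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              int ih = ho * sh - pt + dh;
              if (ih < 0 || ih >= H) continue;
              double v = xp[ih + H * iw];
              if (v > best) { best = v; bi = ih + H * iw; }
            }
          }
          yp[ho + Ho * wo] = best;
          ap[ho + Ho * wo] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(NumericVector gy, IntegerVector am,
                             IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  R_xlen_t plane_o = (R_xlen_t)Ho * Wo, plane_i = (R_xlen_t)H * W;
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* gp = gy.begin() + plane_o * cn;
    const int* ap = am.begin() + plane_o * cn;
    double* xp = gx.begin() + plane_i * cn;
    for (R_xlen_t q = 0; q < plane_o; ++q)
      if (ap[q] >= 0) xp[ap[q]] += gp[q];
  }
  return gx;
}

// Average pooling, padding excluded from the divisor (TF convention).
// [[Rcpp::export]]
NumericVector nn_avgpool_fwd(NumericVector x, int kh, int kw, int sh, int sw,
                             int pt, int pl, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xp = x.begin() + (R_xlen_t)H * W * cn;
    double* yp = y.begin() + (R_xlen_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double s = 0.0; int cnt = 0;
        for (int dw = 0; dw < kw; ++dw) {
          int iw = wo * sw - pl + dw;
          if (iw < 0 || iw >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int ih = ho * sh - pt + dh;
            if (ih < 0 || ih >= H) continue;
            s += xp[ih + H * iw]; ++cnt;
          }
        }
        yp[ho + Ho * wo] = cnt > 0 ? s / cnt : 0.0;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_avgpool_bwd(NumericVector gy, IntegerVector xdim,
                             int kh, int kw, int sh, int sw, int pt, int pl) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    double* xp = gx.begin() + (R_xlen_t)H * W * cn;
    const double* gp = gy.begin() + (R_xlen_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int cnt = 0;
        for (int dw = 0; dw < kw; ++dw) {
          int iw = wo * sw - pl + dw;
          if (iw < 0 || iw >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int ih = ho * sh - pt + dh;
            if (ih >= 0 && ih < H) ++cnt;
          }
        }
        if (cnt == 0) continue;
        double g = gp[ho + Ho * wo] / cnt;
        for (int dw = 0; dw < kw; ++dw) {
          int iw = wo * sw - pl + dw;
          if (iw < 0 || iw >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int ih = ho * sh - pt + dh;
            if (ih >= 0 && ih < H) xp[ih + H * iw] += g;
          }
        }
      }
  }
  return gx;
}

// [[Rcpp::export]]
List nn_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector mean_in, NumericVector var_in,
               bool use_batch_stats, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  R_xlen_t plane = (R_xlen_t)H * W;
  NumericVector y(x.size()); y.attr("dim") = xd;
  NumericVector m(C), v(C);
  if (use_batch_stats) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
        for (R_xlen_t q = 0; q < plane; ++q) { s += xp[q]; s2 += xp[q] * xp[q]; }
      }
      double cnt = (double)plane * N;
      m[c] = s / cnt;
      v[c] = s2 / cnt - m[c] * m[c];
      if (v[c] < 0) v[c] = 0;
    }
  } else {
    m = clone(mean_in); v = clone(var_in);
  }
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(v[c] + eps);
    double g = gamma[c], bb = beta[c], mm = m[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
      double* yp = y.begin() + plane * (c + (R_xlen_t)C * n);
      for (R_xlen_t q = 0; q < plane; ++q)
        yp[q] = g * (xp[q] - mm) * inv + bb;
    }
  }
  return List::create(_["y"] = y, _["mean"] = m, _["var"] = v);
}

// [[Rcpp::export]]
List nn_bn_bwd(NumericVector x, NumericVector gamma, NumericVector m,
               NumericVector v, NumericVector gy, double eps,
               bool batch_stats) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  R_xlen_t plane = (R_xlen_t)H * W;
  double cnt = (double)plane * N;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gg(C), gb(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(v[c] + eps);
    double sum_gy = 0.0, sum_gy_xhat = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
      const double* gp = gy.begin() + plane * (c + (R_xlen_t)C * n);
      for (R_xlen_t q = 0; q < plane; ++q) {
        double xh = (xp[q] - m[c]) * inv;
        sum_gy += gp[q];
        sum_gy_xhat += gp[q] * xh;
      }
    }
    gg[c] = sum_gy_xhat; gb[c] = sum_gy;
    double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
      const double* gp = gy.begin() + plane * (c + (R_xlen_t)C * n);
      double* op = gx.begin() + plane * (c + (R_xlen_t)C * n);
      for (R_xlen_t q = 0; q < plane; ++q) {
        double xh = (xp[q] - m[c]) * inv;
        if (batch_stats)
          op[q] = g * inv * (gp[q] - sum_gy / cnt - xh * sum_gy_xhat / cnt);
        else
          op[q] = g * inv * gp[q];
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = gg, _["gbeta"] = gb);
}

// Bilinear resize with half-pixel centers (TF2 default).
static void resize_coeffs(int in, int out, std::vector<int>& i0,
                          std::vector<int>& i1, std::vector<double>& f) {
  i0.resize(out); i1.resize(out); f.resize(out);
  double scale = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, in - 1);
    i0[o] = lo; i1[o] = hi; f[o] = src - lo;
  }
}

// [[Rcpp::export]]
NumericVector nn_resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  std::vector<int> h0, h1, w0, w1; std::vector<double> fh, fw;
  resize_coeffs(H, Ho, h0, h1, fh);
  resize_coeffs(W, Wo, w0, w1, fw);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xp = x.begin() + (R_xlen_t)H * W * cn;
    double* yp = y.begin() + (R_xlen_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      double a = fw[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        double b = fh[ho];
        double v00 = xp[h0[ho] + H * w0[wo]], v10 = xp[h1[ho] + H * w0[wo]];
        double v01 = xp[h0[ho] + H * w1[wo]], v11 = xp[h1[ho] + H * w1[wo]];
        yp[ho + Ho * wo] = (1 - a) * ((1 - b) * v00 + b * v10) +
                           a * ((1 - b) * v01 + b * v11);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_resize_bilinear_bwd(NumericVector gy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  std::vector<int> h0, h1, w0, w1; std::vector<double> fh, fw;
  resize_coeffs(H, Ho, h0, h1, fh);
  resize_coeffs(W, Wo, w0, w1, fw);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    double* xp = gx.begin() + (R_xlen_t)H * W * cn;
    const double* gp = gy.begin() + (R_xlen_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      double a = fw[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        double b = fh[ho], g = gp[ho + Ho * wo];
        xp[h0[ho] + H * w0[wo]] += (1 - a) * (1 - b) * g;
        xp[h1[ho] + H * w0[wo]] += (1 - a) * b * g;
        xp[h0[ho] + H * w1[wo]] += a * (1 - b) * g;
        xp[h1[ho] + H * w1[wo]] += a * b * g;
      }
    }
  }
  return gx;
}

// Non-local means on an H x W x 3 image in [0,1]. Patch distances for every
// search offset are obtained from an integral image of squared differences,
// so cost is O(HW * search^2) independent of the template size.
// [[Rcpp::export]]
NumericVector nlm_denoise_rgb(NumericVector img, int template_radius,
                              int search_radius, double h) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  NumericVector out(img.size()); out.attr("dim") = d;
  std::vector<double> wsum((size_t)H * W, 0.0);
  std::vector<double> acc((size_t)H * W * C, 0.0);
  int P = (2 * template_radius + 1) * (2 * template_radius + 1) * C;
  double h2 = h * h * P;  // normalise by patch size so h is per-pixel
  std::vector<double> integ((size_t)(H + 1) * (W + 1));
  for (int dy = -search_radius; dy <= search_radius; ++dy) {
    for (int dx = -search_radius; dx <= search_radius; ++dx) {
      // integral image of sum_c (I(p) - I(p+d))^2, out-of-range treated as 0 diff
      for (int j = 0; j <= W; ++j) integ[(size_t)j * (H + 1)] = 0.0;
      for (int i = 0; i <= H; ++i) integ[i] = 0.0;
      for (int j = 1; j <= W; ++j) {
        for (int i = 1; i <= H; ++i) {
          int y = i - 1, x = j - 1;
          int yy = y + dy, xx = x + dx;
          double ssd = 0.0;
          if (yy >= 0 && yy < H && xx >= 0 && xx < W) {
            for (int c = 0; c < C; ++c) {
              double diff = img[y + H * x + (size_t)H * W * c] -
                            img[yy + H * xx + (size_t)H * W * c];
              ssd += diff * diff;
            }
          }
          integ[(size_t)j * (H + 1) + i] = ssd +
            integ[(size_t)(j - 1) * (H + 1) + i] +
            integ[(size_t)j * (H + 1) + i - 1] -
            integ[(size_t)(j - 1) * (H + 1) + i - 1];
        }
      }
      for (int x = 0; x < W; ++x) {
        int x0 = std::max(0, x - template_radius);
        int x1 = std::min(W - 1, x + template_radius);
        for (int y = 0; y < H; ++y) {
          int yy = y + dy, xx = x + dx;
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          int y0 = std::max(0, y - template_radius);
          int y1 = std::min(H - 1, y + template_radius);
          double d2 = integ[(size_t)(x1 + 1) * (H + 1) + y1 + 1] -
                      integ[(size_t)x0 * (H + 1) + y1 + 1] -
                      integ[(size_t)(x1 + 1) * (H + 1) + y0] +
                      integ[(size_t)x0 * (H + 1) + y0];
          double wgt = std::exp(-d2 / h2);
          wsum[y + (size_t)H * x] += wgt;
          for (int c = 0; c < C; ++c)
            acc[y + (size_t)H * x + (size_t)H * W * c] +=
              wgt * img[yy + H * xx + (size_t)H * W * c];
        }
      }
    }
  }
  for (int c = 0; c < C; ++c)
    for (size_t q = 0; q < (size_t)H * W; ++q)
      out[q + (size_t)H * W * c] = acc[q + (size_t)H * W * c] / wsum[q];
  return out;
}
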