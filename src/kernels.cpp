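// Numerical kernels for the network engine and image geometry.
// Array layout throughout: R column-major arrays dim (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

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

// im2col for stride-1 'same' convolution with zero padding.
// K(r, j): r = kh + k*kw + k*k*ci, j = h + H*w  (output position)
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& K) {
  const int k2 = k * k;
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k2 * ci;
        for (int w = 0; w < W; ++w) {
          const int wi = w + kw - pad;
          double* Kcol = K.memptr() + (size_t)r;
          if (wi < 0 || wi >= W) {
            for (int h = 0; h < H; ++h) K((size_t)r, (size_t)(h + H * w)) = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          for (int h = 0; h < H; ++h) {
            const int hi = h + kh - pad;
            K((size_t)r, (size_t)(h + H * w)) =
              (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
        }
      }
    }
  }
  }

static void col2im_acc(const arma::mat& K, int H, int W, int C, int k, int pad,
                       double* gx) {
  const int k2 = k * k;
  for (int ci = 0; ci < C; ++ci) {
    double* gc = gx + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k2 * ci;
        for (int w = 0; w < W; ++w) {
          const int wi = w + kw - pad;
          if (wi < 0 || wi >= W) continue;
          double* gcol = gc + (size_t)wi * H;
          for (int h = 0; h < H; ++h) {
            const int hi = h + kh - pad;
            if (hi < 0 || hi >= H) continue;
            gcol[hi] += K((size_t)r, (size_t)(h + H * w));
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".nn_conv2d_fw")]]
NumericVector nn_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2, k2 = k * k;
  NumericVector y = num4(H, W, Cout, N);
  arma::mat Wt(const_cast<double*>(w.begin()), (size_t)k2 * C, Cout, false, true);
  arma::mat K((size_t)k2 * C, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, K);
    arma::mat Y = Wt.t() * K;  // Cout x HW
    double* yp = y.begin() + (size_t)n * H * W * Cout;
    for (int o = 0; o < Cout; ++o) {
      const double bo = b[o];
      for (size_t j = 0; j < (size_t)H * W; ++j)
        yp[(size_t)o * H * W + j] = Y((size_t)o, j) + bo;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".nn_conv2d_bw")]]
List nn_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2, k2 = k * k;
  NumericVector gx = num4(H, W, C, N);
  NumericVector gw = num4(k, k, C, Cout);
  NumericVector gb(Cout);
  arma::mat Wt(const_cast<double*>(w.begin()), (size_t)k2 * C, Cout, false, true);
  arma::mat gW((size_t)k2 * C, Cout, arma::fill::zeros);
  arma::mat K((size_t)k2 * C, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, K);
    arma::mat gY(Cout, (size_t)H * W);
    const double* gp = gy.begin() + (size_t)n * H * W * Cout;
    for (int o = 0; o < Cout; ++o)
      for (size_t j = 0; j < (size_t)H * W; ++j)
        gY((size_t)o, j) = gp[(size_t)o * H * W + j];
    gW += K * gY.t();
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(gY.row(o));
    arma::mat gK = Wt * gY;
    col2im_acc(gK, H, W, C, k, pad, gx.begin() + (size_t)n * H * W * C);
  }
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gw.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2x2, stride 2 (non-overlapping blocks).
// w dim (2, 2, Cin, Cout); y[2h+kh, 2w+kw, o, n] = sum_ci x[h,w,ci,n] w[kh,kw,ci,o] + b[o]
// [[Rcpp::export(name = ".nn_convt2_fw")]]
NumericVector nn_convt2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y = num4(H2, W2, Cout, N);
  // Wm(ci, kh + 2*kw + 4*o) from w(kh,kw,ci,o)
  arma::mat Wm(C, 4 * Cout);
  for (int o = 0; o < Cout; ++o)
    for (int ci = 0; ci < C; ++ci)
      for (int kw = 0; kw < 2; ++kw)
        for (int kh = 0; kh < 2; ++kh)
          Wm(ci, kh + 2 * kw + 4 * o) =
            w[kh + 2 * (kw + 2 * ((size_t)ci + (size_t)C * o))];
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                (size_t)H * W, C, false, true);
    arma::mat Y = X * Wm;  // HW x 4Cout
    double* yp = y.begin() + (size_t)n * H2 * W2 * Cout;
    for (int o = 0; o < Cout; ++o) {
      const double bo = b[o];
      for (int w_ = 0; w_ < W; ++w_)
        for (int h = 0; h < H; ++h) {
          const size_t j = (size_t)h + (size_t)H * w_;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              yp[(size_t)(2 * h + kh) + (size_t)H2 * (2 * w_ + kw) +
                 (size_t)H2 * W2 * o] = Y(j, kh + 2 * kw + 4 * o) + bo;
        }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".nn_convt2_bw")]]
List nn_convt2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector gx = num4(H, W, C, N);
  NumericVector gw = num4(2, 2, C, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(C, 4 * Cout);
  for (int o = 0; o < Cout; ++o)
    for (int ci = 0; ci < C; ++ci)
      for (int kw = 0; kw < 2; ++kw)
        for (int kh = 0; kh < 2; ++kh)
          Wm(ci, kh + 2 * kw + 4 * o) =
            w[kh + 2 * (kw + 2 * ((size_t)ci + (size_t)C * o))];
  arma::mat gWm(C, 4 * Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat gY((size_t)H * W, 4 * Cout);
    const double* gp = gy.begin() + (size_t)n * H2 * W2 * Cout;
    for (int o = 0; o < Cout; ++o)
      for (int w_ = 0; w_ < W; ++w_)
        for (int h = 0; h < H; ++h)
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              gY((size_t)h + (size_t)H * w_, kh + 2 * kw + 4 * o) =
                gp[(size_t)(2 * h + kh) + (size_t)H2 * (2 * w_ + kw) +
                   (size_t)H2 * W2 * o];
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                (size_t)H * W, C, false, true);
    gWm += X.t() * gY;
    arma::mat gX = gY * Wm.t();  // HW x C
    double* gxp = gx.begin() + (size_t)n * H * W * C;
    for (int ci = 0; ci < C; ++ci)
      for (size_t j = 0; j < (size_t)H * W; ++j)
        gxp[(size_t)ci * H * W + j] += gX(j, ci);
    for (int o = 0; o < Cout; ++o)
      for (int q = 0; q < 4; ++q) gb[o] += arma::accu(gY.col(q + 4 * o));
  }
  for (int o = 0; o < Cout; ++o)
    for (int ci = 0; ci < C; ++ci)
      for (int kw = 0; kw < 2; ++kw)
        for (int kh = 0; kh < 2; ++kh)
          gw[kh + 2 * (kw + 2 * ((size_t)ci + (size_t)C * o))] =
            gWm(ci, kh + 2 * kw + 4 * o);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. idx stores the argmax offset (dh + 2*dw).
// [[Rcpp::export(name = ".nn_maxpool2_fw")]]
List nn_maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = num4(Ho, Wo, C, N);
  IntegerVector idx = int4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -1e300; int bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              double v = xp[(size_t)(2 * h + dh) + (size_t)H * (2 * w + dw)];
              if (v > best) { best = v; bi = dh + 2 * dw; }
            }
          yp[(size_t)h + (size_t)Ho * w] = best;
          ip[(size_t)h + (size_t)Ho * w] = bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".nn_maxpool2_bw")]]
NumericVector nn_maxpool2_bw(NumericVector gy, IntegerVector idx, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx = num4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* gxp = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const int bi = ip[(size_t)h + (size_t)Ho * w];
          const int dh = bi % 2, dw = bi / 2;
          gxp[(size_t)(2 * h + dh) + (size_t)H * (2 * w + dw)] +=
            gp[(size_t)h + (size_t)Ho * w];
        }
    }
  return gx;
}

// Inverse-mapped affine warp of a single-channel image.
// minv is the 2x3 matrix mapping output coords to input coords,
// (xi, yi) = minv %*% c(xo, yo, 1), with x = column, y = row, 0-based.
// [[Rcpp::export(name = ".warp_affine_cpp")]]
NumericMatrix warp_affine_cpp(NumericMatrix img, NumericMatrix minv,
                              bool bilinear, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double a = minv(0, 0), bq = minv(0, 1), tx = minv(0, 2);
  const double c = minv(1, 0), d = minv(1, 1), ty = minv(1, 2);
  for (int wo = 0; wo < W; ++wo)
    for (int ho = 0; ho < H; ++ho) {
      const double xi = a * wo + bq * ho + tx;
      const double yi = c * wo + d * ho + ty;
      double v = fill;
      if (bilinear) {
        const int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
        const double fx = xi - x0, fy = yi - y0;
        double acc = 0.0; bool any = false;
        const double wts[4] = {(1 - fx) * (1 - fy), fx * (1 - fy),
                               (1 - fx) * fy, fx * fy};
        const int xs[4] = {x0, x0 + 1, x0, x0 + 1};
        const int ys[4] = {y0, y0, y0 + 1, y0 + 1};
        for (int q = 0; q < 4; ++q) {
          double pv = fill;
          if (xs[q] >= 0 && xs[q] < W && ys[q] >= 0 && ys[q] < H) {
            pv = img(ys[q], xs[q]); any = true;
          }
          acc += wts[q] * pv;
        }
        v = any ? acc : fill;
      } else {
        const int xn = (int)std::lround(xi), yn = (int)std::lround(yi);
        if (xn >= 0 && xn < W && yn >= 0 && yn < H) v = img(yn, xn);
      }
      out(ho, wo) = v;
    }
  return out;
}

// Plain resize of a single-channel image (align-corners = FALSE convention).
// [[Rcpp::export(name = ".resize2d_cpp")]]
NumericMatrix resize2d_cpp(NumericMatrix img, int H2, int W2, bool bilinear) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H2, W2);
  const double sy = (double)H / H2, sx = (double)W / W2;
  for (int wo = 0; wo < W2; ++wo)
    for (int ho = 0; ho < H2; ++ho) {
      const double yi = (ho + 0.5) * sy - 0.5, xi = (wo + 0.5) * sx - 0.5;
      if (bilinear) {
        int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
        const double fx = xi - x0, fy = yi - y0;
        const int x1 = std::min(std::max(x0 + 1, 0), W - 1);
        const int y1 = std::min(std::max(y0 + 1, 0), H - 1);
        x0 = std::min(std::max(x0, 0), W - 1);
        y0 = std::min(std::max(y0, 0), H - 1);
        out(ho, wo) = (1 - fx) * (1 - fy) * img(y0, x0) +
                      fx * (1 - fy) * img(y0, x1) +
                      (1 - fx) * fy * img(y1, x0) + fx * fy * img(y1, x1);
      } else {
        int xn = (int)std::lround(xi), yn = (int)std::lround(yi);
        xn = std::min(std::max(xn, 0), W - 1);
        yn = std::min(std::max(yn, 0), H - 1);
        out(ho, wo) = img(yn, xn);
      }
    }
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes. Input: binary matrix; output: for each
// pixel, squared distance to the nearest foreground (nonzero) pixel.
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -1e300; z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericMatrix edt_sq_cpp(NumericMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix g(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) f[h] = mask(h, w) != 0 ? 0.0 : 1e300;
    edt1d(f, d, H);
    for (int h = 0; h < H; ++h) g(h, w) = d[h];
  }
  NumericMatrix out(H, W);
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) f[w] = g(h, w);
    edt1d(f, d, W);
    for (int w = 0; w < W; ++w) out(h, w) = d[w];
  }
  return out;
}

// CRC-32 (IEEE) over a raw vector; needed by the 16-bit PNG writer.
// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int j = 0; j < 8; ++j) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

// Batch-norm helpers: per-channel stats over (H, W, N).
// [[Rcpp::export(name = ".nn_bn_stats")]]
List nn_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      for (size_t j = 0; j < hw; ++j) { s += p[j]; s2 += p[j] * p[j]; }
    }
    const double m = s / (hw * N);
    mu[c] = m;
    va[c] = std::max(s2 / (hw * N) - m * m, 0.0);
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export(name = ".nn_bn_fw")]]
NumericVector nn_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
                       NumericVector mu, NumericVector va, double eps) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y = num4(xd[0], xd[1], C, N);
  for (int c = 0; c < C; ++c) {
    const double sc = gamma[c] / std::sqrt(va[c] + eps);
    const double sh = beta[c] - mu[c] * sc;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double* q = y.begin() + hw * (c + (size_t)C * n);
      for (size_t j = 0; j < hw; ++j) q[j] = p[j] * sc + sh;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".nn_bn_bw")]]
List nn_bn_bw(NumericVector x, NumericVector gamma, NumericVector mu,
              NumericVector va, NumericVector gy, bool training, double eps) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double m = (double)hw * N;
  NumericVector gx = num4(xd[0], xd[1], C, N);
  NumericVector gg(C), gb(C);
  for (int c = 0; c < C; ++c) {
    const double isd = 1.0 / std::sqrt(va[c] + eps);
    double sum_g = 0.0, sum_gx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + hw * (c + (size_t)C * n);
      const double* pg = gy.begin() + hw * (c + (size_t)C * n);
      for (size_t j = 0; j < hw; ++j) {
        sum_g += pg[j];
        sum_gx += pg[j] * (px[j] - mu[c]) * isd;
      }
    }
    gg[c] = sum_gx; gb[c] = sum_g;
    const double k = gamma[c] * isd;
    if (training) {
      const double a = sum_g / m, b = sum_gx / m;
      for (int n = 0; n < N; ++n) {
        const double* px = x.begin() + hw * (c + (size_t)C * n);
        const double* pg = gy.begin() + hw * (c + (size_t)C * n);
        double* pq = gx.begin() + hw * (c + (size_t)C * n);
        for (size_t j = 0; j < hw; ++j)
          pq[j] = k * (pg[j] - a - (px[j] - mu[c]) * isd * b);
      }
    } else {
      for (int n = 0; n < N; ++n) {
        const double* pg = gy.begin() + hw * (c + (size_t)C * n);
        double* pq = gx.begin() + hw * (c + (size_t)C * n);
        for (size_t j = 0; j < hw; ++j) pq[j] = k * pg[j];
      }
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// [[Rcpp::export(name = ".nn_relu_fw")]]
NumericVector nn_relu_fw(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return y;
}

// [[Rcpp::export(name = ".nn_relu_bw")]]
NumericVector nn_relu_bw(NumericVector x, NumericVector gy) {
  NumericVector g = clone(gy);
  for (R_xlen_t i = 0; i < g.size(); ++i) if (x[i] <= 0) g[i] = 0;
  return g;
}
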