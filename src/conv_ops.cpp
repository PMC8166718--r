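// Low-level neural-network kernels for the segmentation models.
//
// Layout conventions (match R's column-major arrays):
//   feature maps  : dim (h, w, c, n)          -- spatial, channel, batch
//   3x3 weights   : matrix (9*c_in, c_out), row = k*9 + dx*3 + dy
//   2x2 up weights: matrix (c_in, 4*c_out),  col = k*4 + dx*2 + dy
//
// Convolutions run in single precision internally (im2col + SGEMM, the
// standard numerical regime for CNN training) with double-precision R
// interfaces; batch normalization is fused two-pass double code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector& x, int& h, int& w, int& c,
                         int& n) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (h, w, c, n)");
  h = d[0]; w = d[1]; c = d[2]; n = d[3];
}

// im2col for a 3x3 kernel (pad 0 or 1), casting to float.
static arma::fmat im2col3f(const double* x, int h, int w, int c, int n,
                           int pad) {
  const int ho = h + 2 * pad - 2, wo = w + 2 * pad - 2;
  arma::fmat col(static_cast<size_t>(ho) * wo * n, 9 * c,
                 arma::fill::zeros);
  const size_t plane = static_cast<size_t>(h) * w;
  const size_t vol = plane * c;
  for (int k = 0; k < c; ++k)
    for (int dx = 0; dx < 3; ++dx)
      for (int dy = 0; dy < 3; ++dy) {
        const int cc = k * 9 + dx * 3 + dy;
        float* dst0 = col.colptr(cc);
        const int oi0 = std::max(0, pad - dy);
        const int oi1 = std::min(ho, h + pad - dy);
        const int oj0 = std::max(0, pad - dx);
        const int oj1 = std::min(wo, w + pad - dx);
        if (oi1 <= oi0 || oj1 <= oj0) continue;
        for (int l = 0; l < n; ++l) {
          const double* xs = x + vol * l + plane * k;
          for (int oj = oj0; oj < oj1; ++oj) {
            const int j = oj - pad + dx;
            const double* src = xs + static_cast<size_t>(h) * j +
              (oi0 - pad + dy);
            float* dst = dst0 + static_cast<size_t>(ho) * oj +
              static_cast<size_t>(ho) * wo * l + oi0;
            for (int i = 0; i < oi1 - oi0; ++i)
              dst[i] = static_cast<float>(src[i]);
          }
        }
      }
  return col;
}

static arma::fmat as_fmat(const NumericMatrix& m) {
  arma::fmat f(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), f.begin());
  return f;
}

// [[Rcpp::export(name = ".cpp_conv3_fwd")]]
NumericVector cpp_conv3_fwd(NumericVector x, NumericMatrix wmat,
                            NumericVector bias, int pad) {
  int h, w, c, n; dims4(x, h, w, c, n);
  const int co = wmat.ncol();
  if (wmat.nrow() != 9 * c) stop("weight rows != 9 * c_in");
  const int ho = h + 2 * pad - 2, wo = w + 2 * pad - 2;
  if (ho < 1 || wo < 1) stop("spatial dims too small for 3x3 kernel");
  arma::fmat col = im2col3f(REAL(x), h, w, c, n, pad);
  arma::fmat y = col * as_fmat(wmat);
  NumericVector out(static_cast<R_xlen_t>(ho) * wo * co * n);
  out.attr("dim") = IntegerVector::create(ho, wo, co, n);
  double* op = REAL(out);
  const size_t oplane = static_cast<size_t>(ho) * wo;
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < co; ++k) {
      const double b = bias[k];
      double* dst = op + oplane * co * l + oplane * k;
      const float* src = y.colptr(k) + oplane * l;
      for (size_t i = 0; i < oplane; ++i) dst[i] = src[i] + b;
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv3_bwd")]]
List cpp_conv3_bwd(NumericVector x, NumericMatrix wmat, NumericVector dy,
                   int pad) {
  int h, w, c, n; dims4(x, h, w, c, n);
  const int co = wmat.ncol();
  const int ho = h + 2 * pad - 2, wo = w + 2 * pad - 2;
  const size_t oplane = static_cast<size_t>(ho) * wo;
  arma::fmat dym(oplane * n, co);
  const double* dp = REAL(dy);
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < co; ++k) {
      const double* src = dp + oplane * co * l + oplane * k;
      float* dst = dym.colptr(k) + oplane * l;
      for (size_t i = 0; i < oplane; ++i)
        dst[i] = static_cast<float>(src[i]);
    }
  arma::fmat col = im2col3f(REAL(x), h, w, c, n, pad);
  arma::fmat wa = as_fmat(wmat);
  arma::fmat dW = col.t() * dym;
  arma::frowvec db = arma::sum(dym, 0);
  arma::fmat dcol = dym * wa.t();
  NumericVector dx(static_cast<R_xlen_t>(h) * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  double* dxp = REAL(dx);
  const size_t plane = static_cast<size_t>(h) * w;
  const size_t vol = plane * c;
  for (int k = 0; k < c; ++k)
    for (int dxi = 0; dxi < 3; ++dxi)
      for (int dyi = 0; dyi < 3; ++dyi) {
        const int cc = k * 9 + dxi * 3 + dyi;
        const float* dc0 = dcol.colptr(cc);
        const int oi0 = std::max(0, pad - dyi);
        const int oi1 = std::min(ho, h + pad - dyi);
        const int oj0 = std::max(0, pad - dxi);
        const int oj1 = std::min(wo, w + pad - dxi);
        if (oi1 <= oi0 || oj1 <= oj0) continue;
        for (int l = 0; l < n; ++l) {
          double* xs = dxp + vol * l + plane * k;
          for (int oj = oj0; oj < oj1; ++oj) {
            const int j = oj - pad + dxi;
            const float* src = dc0 + static_cast<size_t>(ho) * oj +
              oplane * l + oi0;
            double* dst = xs + static_cast<size_t>(h) * j +
              (oi0 - pad + dyi);
            for (int i = 0; i < oi1 - oi0; ++i) dst[i] += src[i];
          }
        }
      }
  NumericMatrix dWr(9 * c, co);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(co);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = dbr);
}

// -- gather/scatter between (h,w,c,n) arrays and (h*w*n) x c float mats ------

static arma::fmat gather_cmat(const double* x, int h, int w, int c, int n) {
  const size_t plane = static_cast<size_t>(h) * w;
  arma::fmat m(plane * n, c);
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < c; ++k) {
      const double* src = x + plane * c * l + plane * k;
      float* dst = m.colptr(k) + plane * l;
      for (size_t i = 0; i < plane; ++i)
        dst[i] = static_cast<float>(src[i]);
    }
  return m;
}

static void scatter_cmat(const arma::fmat& m, double* out, int h, int w,
                         int c, int n) {
  const size_t plane = static_cast<size_t>(h) * w;
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < c; ++k) {
      const float* src = m.colptr(k) + plane * l;
      double* dst = out + plane * c * l + plane * k;
      for (size_t i = 0; i < plane; ++i) dst[i] = src[i];
    }
}

// 1x1 convolution (channel mixing).
// [[Rcpp::export(name = ".cpp_conv1_fwd")]]
NumericVector cpp_conv1_fwd(NumericVector x, NumericMatrix wmat,
                            NumericVector bias) {
  int h, w, c, n; dims4(x, h, w, c, n);
  if (wmat.nrow() != c) stop("weight rows != c_in");
  const int co = wmat.ncol();
  arma::fmat y = gather_cmat(REAL(x), h, w, c, n) * as_fmat(wmat);
  NumericVector out(static_cast<R_xlen_t>(h) * w * co * n);
  out.attr("dim") = IntegerVector::create(h, w, co, n);
  const size_t plane = static_cast<size_t>(h) * w;
  double* op = REAL(out);
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < co; ++k) {
      const float* src = y.colptr(k) + plane * l;
      double* dst = op + plane * co * l + plane * k;
      const double b = bias[k];
      for (size_t i = 0; i < plane; ++i) dst[i] = src[i] + b;
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv1_bwd")]]
List cpp_conv1_bwd(NumericVector x, NumericMatrix wmat, NumericVector dy) {
  int h, w, c, n; dims4(x, h, w, c, n);
  const int co = wmat.ncol();
  arma::fmat xm = gather_cmat(REAL(x), h, w, c, n);
  arma::fmat dym = gather_cmat(REAL(dy), h, w, co, n);
  arma::fmat wa = as_fmat(wmat);
  arma::fmat dW = xm.t() * dym;
  arma::fmat dxm = dym * wa.t();
  arma::frowvec db = arma::sum(dym, 0);
  NumericVector dx(static_cast<R_xlen_t>(h) * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  scatter_cmat(dxm, REAL(dx), h, w, c, n);
  NumericMatrix dWr(c, co);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(co);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = dbr);
}

// 2x2 stride-2 transposed convolution.
// [[Rcpp::export(name = ".cpp_upconv2_fwd")]]
NumericVector cpp_upconv2_fwd(NumericVector x, NumericMatrix wmat,
                              NumericVector bias) {
  int h, w, c, n; dims4(x, h, w, c, n);
  if (wmat.nrow() != c) stop("weight rows != c_in");
  const int co = wmat.ncol() / 4;
  const size_t plane = static_cast<size_t>(h) * w;
  arma::fmat y = gather_cmat(REAL(x), h, w, c, n) * as_fmat(wmat);
  const int H = 2 * h, W2 = 2 * w;
  NumericVector out(static_cast<R_xlen_t>(H) * W2 * co * n);
  out.attr("dim") = IntegerVector::create(H, W2, co, n);
  double* op = REAL(out);
  const size_t Oplane = static_cast<size_t>(H) * W2;
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < co; ++k) {
      double* dst = op + Oplane * co * l + Oplane * k;
      const double b = bias[k];
      for (int dxi = 0; dxi < 2; ++dxi)
        for (int dyi = 0; dyi < 2; ++dyi) {
          const float* src = y.colptr(k * 4 + dxi * 2 + dyi) + plane * l;
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i)
              dst[(2 * i + dyi) + static_cast<size_t>(H) * (2 * j + dxi)] =
                src[i + static_cast<size_t>(h) * j] + b;
        }
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_upconv2_bwd")]]
List cpp_upconv2_bwd(NumericVector x, NumericMatrix wmat, NumericVector dy) {
  int h, w, c, n; dims4(x, h, w, c, n);
  const int co = wmat.ncol() / 4;
  const int H = 2 * h, W2 = 2 * w;
  const size_t plane = static_cast<size_t>(h) * w;
  const size_t Oplane = static_cast<size_t>(H) * W2;
  arma::fmat dym(plane * n, 4 * co);
  const double* dp = REAL(dy);
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < co; ++k) {
      const double* src = dp + Oplane * co * l + Oplane * k;
      for (int dxi = 0; dxi < 2; ++dxi)
        for (int dyi = 0; dyi < 2; ++dyi) {
          float* dst = dym.colptr(k * 4 + dxi * 2 + dyi) + plane * l;
          for (int j = 0; j < w; ++j)
            for (int i = 0; i < h; ++i)
              dst[i + static_cast<size_t>(h) * j] = static_cast<float>(
                src[(2 * i + dyi) + static_cast<size_t>(H) * (2 * j + dxi)]);
        }
    }
  arma::fmat xm = gather_cmat(REAL(x), h, w, c, n);
  arma::fmat wa = as_fmat(wmat);
  arma::fmat dW = xm.t() * dym;
  arma::fmat dxm = dym * wa.t();
  NumericVector dx(static_cast<R_xlen_t>(h) * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  scatter_cmat(dxm, REAL(dx), h, w, c, n);
  NumericVector db(co);
  for (int k = 0; k < co; ++k)
    for (int t = 0; t < 4; ++t) db[k] += arma::accu(dym.col(k * 4 + t));
  NumericMatrix dWr(c, 4 * co);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = db);
}

// 2x2 stride-2 max pooling; argmax stored as dy + 2*dx in 0..3.
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  int h, w, c, n; dims4(x, h, w, c, n);
  if (h % 2 || w % 2) stop("maxpool requires even spatial dims");
  const int ho = h / 2, wo = w / 2;
  NumericVector y(static_cast<R_xlen_t>(ho) * wo * c * n);
  IntegerVector arg(y.size());
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const size_t plane = static_cast<size_t>(h) * w;
  const size_t oplane = static_cast<size_t>(ho) * wo;
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < c; ++k) {
      const double* src = xp + plane * c * l + plane * k;
      for (int oj = 0; oj < wo; ++oj)
        for (int oi = 0; oi < ho; ++oi) {
          int best = 0;
          double bv = -std::numeric_limits<double>::infinity();
          for (int dxi = 0; dxi < 2; ++dxi)
            for (int dyi = 0; dyi < 2; ++dyi) {
              const double v = src[(2 * oi + dyi) +
                                   static_cast<size_t>(h) * (2 * oj + dxi)];
              if (v > bv) { bv = v; best = dyi + 2 * dxi; }
            }
          const size_t oidx = oi + static_cast<size_t>(ho) * oj +
            oplane * k + oplane * c * l;
          yp[oidx] = bv;
          arg[oidx] = best;
        }
    }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector arg,
                               IntegerVector dimx) {
  const int h = dimx[0], w = dimx[1], c = dimx[2], n = dimx[3];
  const int ho = h / 2, wo = w / 2;
  NumericVector dx(static_cast<R_xlen_t>(h) * w * c * n);
  dx.attr("dim") = dimx;
  const double* dp = REAL(dy);
  double* dxp = REAL(dx);
  const size_t plane = static_cast<size_t>(h) * w;
  const size_t oplane = static_cast<size_t>(ho) * wo;
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < c; ++k) {
      double* dst = dxp + plane * c * l + plane * k;
      for (int oj = 0; oj < wo; ++oj)
        for (int oi = 0; oi < ho; ++oi) {
          const size_t oidx = oi + static_cast<size_t>(ho) * oj +
            oplane * k + oplane * c * l;
          const int a = arg[oidx];
          dst[(2 * oi + a % 2) +
              static_cast<size_t>(h) * (2 * oj + a / 2)] += dp[oidx];
        }
    }
  return dx;
}

// Fused batch normalization over (h, w, n) per channel.
// [[Rcpp::export(name = ".cpp_bn_fwd")]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, bool training,
                double momentum, double eps) {
  int h, w, c, n; dims4(x, h, w, c, n);
  const size_t plane = static_cast<size_t>(h) * w;
  const size_t vol = plane * c;
  const double m = static_cast<double>(plane) * n;
  NumericVector mu(c), inv(c), nrm(clone(rmean)), nrv(clone(rvar));
  const double* xp = REAL(x);
  for (int k = 0; k < c; ++k) {
    double mk, vk;
    if (training) {
      double s = 0, s2 = 0;
      for (int l = 0; l < n; ++l) {
        const double* src = xp + vol * l + plane * k;
        for (size_t i = 0; i < plane; ++i) {
          s += src[i];
          s2 += src[i] * src[i];
        }
      }
      mk = s / m;
      vk = s2 / m - mk * mk;
      nrm[k] = (1 - momentum) * nrm[k] + momentum * mk;
      nrv[k] = (1 - momentum) * nrv[k] + momentum * vk;
    } else {
      mk = rmean[k];
      vk = rvar[k];
    }
    mu[k] = mk;
    inv[k] = 1.0 / std::sqrt(vk + eps);
  }
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  double* yp = REAL(y);
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < c; ++k) {
      const double* src = xp + vol * l + plane * k;
      double* dst = yp + vol * l + plane * k;
      const double a = gamma[k] * inv[k];
      const double b = beta[k] - a * mu[k];
      for (size_t i = 0; i < plane; ++i) dst[i] = a * src[i] + b;
    }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv"] = inv,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mu, NumericVector inv) {
  int h, w, c, n; dims4(x, h, w, c, n);
  const size_t plane = static_cast<size_t>(h) * w;
  const size_t vol = plane * c;
  const double m = static_cast<double>(plane) * n;
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  NumericVector dgamma(c), dbeta(c);
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  double* dxp = REAL(dx);
  for (int k = 0; k < c; ++k) {
    double t1 = 0, t2 = 0;
    for (int l = 0; l < n; ++l) {
      const double* xs = xp + vol * l + plane * k;
      const double* ds = dp + vol * l + plane * k;
      for (size_t i = 0; i < plane; ++i) {
        const double xh = (xs[i] - mu[k]) * inv[k];
        t1 += ds[i];
        t2 += ds[i] * xh;
      }
    }
    dbeta[k] = t1;
    dgamma[k] = t2;
    const double gi = gamma[k] * inv[k];
    for (int l = 0; l < n; ++l) {
      const double* xs = xp + vol * l + plane * k;
      const double* ds = dp + vol * l + plane * k;
      double* od = dxp + vol * l + plane * k;
      for (size_t i = 0; i < plane; ++i) {
        const double xh = (xs[i] - mu[k]) * inv[k];
        od[i] = gi * (ds[i] - t1 / m - xh * t2 / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
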