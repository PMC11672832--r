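// Low-level tensor kernels for the detection network.
//
// All feature maps are R arrays with dim = c(N, C, H, W); the element
// (n, c, h, w) lives at offset n + N*(c + C*(h + H*w)) (0-based). Convolution
// is realized as im2col + BLAS GEMM per sample and channel group, which keeps
// both the forward pass and the reverse-mode gradients exact and fast on CPU.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill `col` (K x L, K = Cg*kh*kw, L = Ho*Wo) for sample n, group g.
static void im2col(const double* x, int N, int C, int H, int W,
                   int n, int c0, int Cg, int kh, int kw,
                   int stride, int pad, int Ho, int Wo, arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      double* colptr = col.colptr(l);
      for (int j = 0; j < kw; ++j) {
        const int w = wo * stride - pad + j;
        for (int i = 0; i < kh; ++i) {
          const int h = ho * stride - pad + i;
          const bool inside = (h >= 0 && h < H && w >= 0 && w < W);
          const int base = inside ? (n + N * (c0 + C * (h + H * w))) : 0;
          double* dst = colptr + Cg * (i + kh * j);
          if (inside) {
            for (int c = 0; c < Cg; ++c) dst[c] = x[base + N * c];
          } else {
            for (int c = 0; c < Cg; ++c) dst[c] = 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the columns back into dx (inverse of im2col).
static void col2im(const arma::mat& col, double* dx, int N, int C, int H, int W,
                   int n, int c0, int Cg, int kh, int kw,
                   int stride, int pad, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      const double* colptr = col.colptr(l);
      for (int j = 0; j < kw; ++j) {
        const int w = wo * stride - pad + j;
        if (w < 0 || w >= W) continue;
        for (int i = 0; i < kh; ++i) {
          const int h = ho * stride - pad + i;
          if (h < 0 || h >= H) continue;
          const int base = n + N * (c0 + C * (h + H * w));
          const double* src = colptr + Cg * (i + kh * j);
          for (int c = 0; c < Cg; ++c) dx[base + N * c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            Nullable<NumericVector> bias,
                            int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[0], Cg = wd[1], kh = wd[2], kw = wd[3];
  if (C != Cg * groups) stop("conv2d: input channels %d do not match weight %d x %d groups",
                             C, Cg, groups);
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");
  const int Coutg = Cout / groups, K = Cg * kh * kw, L = Ho * Wo;

  NumericVector y(static_cast<R_xlen_t>(N) * Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, Cout, Ho, Wo);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  const double* bp = bias.isNotNull() ? NumericVector(bias).begin() : nullptr;

  arma::mat col(K, L), Wg(Coutg, K), Y;
  for (int g = 0; g < groups; ++g) {
    // weight slice for this group, rows ordered to match im2col's K order
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i)
        for (int c = 0; c < Cg; ++c)
          for (int o = 0; o < Coutg; ++o)
            Wg(o, c + Cg * (i + kh * j)) =
              wp[(g * Coutg + o) + Cout * (c + Cg * (i + kh * j))];
    for (int n = 0; n < N; ++n) {
      im2col(xp, N, C, H, W, n, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, col);
      Y = Wg * col;  // Coutg x L
      for (int o = 0; o < Coutg; ++o) {
        const int oc = g * Coutg + o;
        const double b = bp ? bp[oc] : 0.0;
        for (int l = 0; l < L; ++l) yp[n + N * (oc + Cout * l)] = Y(o, l) + b;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, int groups, bool need_dx,
                   bool need_db) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[0], Cg = wd[1], kh = wd[2], kw = wd[3];
  const int Ho = yd[2], Wo = yd[3];
  const int Coutg = Cout / groups, K = Cg * kh * kw, L = Ho * Wo;

  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;
  NumericVector db(need_db ? Cout : 0);

  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dwp = dw.begin();
  double* dxp = need_dx ? dx.begin() : nullptr;

  arma::mat col(K, L), Wg(Coutg, K), dY(Coutg, L), dWg, dcol;
  for (int g = 0; g < groups; ++g) {
    dWg.zeros(Coutg, K);
    if (need_dx)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          for (int c = 0; c < Cg; ++c)
            for (int o = 0; o < Coutg; ++o)
              Wg(o, c + Cg * (i + kh * j)) =
                wp[(g * Coutg + o) + Cout * (c + Cg * (i + kh * j))];
    for (int n = 0; n < N; ++n) {
      for (int o = 0; o < Coutg; ++o) {
        const int oc = g * Coutg + o;
        for (int l = 0; l < L; ++l) dY(o, l) = dyp[n + N * (oc + Cout * l)];
      }
      im2col(xp, N, C, H, W, n, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, col);
      dWg += dY * col.t();
      if (need_dx) {
        dcol = Wg.t() * dY;
        col2im(dcol, dxp, N, C, H, W, n, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo);
      }
      if (need_db)
        for (int o = 0; o < Coutg; ++o) {
          double s = 0.0;
          for (int l = 0; l < L; ++l) s += dY(o, l);
          db[g * Coutg + o] += s;
        }
    }
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i)
        for (int c = 0; c < Cg; ++c)
          for (int o = 0; o < Coutg; ++o)
            dwp[(g * Coutg + o) + Cout * (c + Cg * (i + kh * j))] =
              dWg(o, c + Cg * (i + kh * j));
  }
  List out = List::create(_["dw"] = dw);
  if (need_dx) out["dx"] = dx;
  if (need_db) out["db"] = db;
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y(static_cast<R_xlen_t>(N) * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  IntegerVector idx(y.size());  // 0-based offset into x of each max
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int j = 0; j < k; ++j) {
            const int w = wo * stride - pad + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int h = ho * stride - pad + i;
              if (h < 0 || h >= H) continue;
              const int off = n + N * (c + C * (h + H * w));
              if (xp[off] > best) { best = xp[off]; besti = off; }
            }
          }
          const int l = n + N * (c + C * (ho + Ho * wo));
          yp[l] = best;
          ip[l] = besti;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector dy,
                             IntegerVector xdim) {
  R_xlen_t nx = 1;
  for (int i = 0; i < 4; ++i) nx *= xdim[i];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  for (R_xlen_t l = 0; l < dy.size(); ++l)
    if (ip[l] >= 0) dxp[ip[l]] += dyp[l];
  return dx;
}

// IEEE 754 binary16 with round-to-nearest-even; used for the half-precision
// checkpoint payload that the size metric is defined on.
static uint16_t f32_to_f16(float f) {
  uint32_t x;
  std::memcpy(&x, &f, 4);
  const uint32_t sign = (x >> 16) & 0x8000u;
  int32_t exp = ((x >> 23) & 0xff) - 127 + 15;
  uint32_t mant = x & 0x7fffffu;
  if (((x >> 23) & 0xff) == 0xff) return sign | 0x7c00u | (mant ? 0x200u : 0u);
  if (exp >= 0x1f) return sign | 0x7c00u;  // overflow -> inf
  if (exp <= 0) {                          // subnormal or zero
    if (exp < -10) return sign;
    mant |= 0x800000u;
    const int shift = 14 - exp;
    uint32_t half = mant >> shift;
    const uint32_t rem = mant & ((1u << shift) - 1), halfway = 1u << (shift - 1);
    if (rem > halfway || (rem == halfway && (half & 1))) ++half;
    return sign | half;
  }
  uint32_t half = (exp << 10) | (mant >> 13);
  const uint32_t rem = mant & 0x1fffu;
  if (rem > 0x1000u || (rem == 0x1000u && (half & 1))) ++half;
  return sign | half;
}

static float f16_to_f32(uint16_t h) {
  const uint32_t sign = (h & 0x8000u) << 16;
  uint32_t exp = (h >> 10) & 0x1f, mant = h & 0x3ffu;
  uint32_t x;
  if (exp == 0) {
    if (mant == 0) x = sign;
    else {
      exp = 127 - 15 + 1;
      while (!(mant & 0x400u)) { mant <<= 1; --exp; }
      mant &= 0x3ffu;
      x = sign | (exp << 23) | (mant << 13);
    }
  } else if (exp == 0x1f) {
    x = sign | 0x7f800000u | (mant << 13);
  } else {
    x = sign | ((exp - 15 + 127) << 23) | (mant << 13);
  }
  float f;
  std::memcpy(&f, &x, 4);
  return f;
}

// [[Rcpp::export]]
RawVector cpp_fp16_pack(NumericVector x) {
  RawVector out(2 * x.size());
  uint16_t* p = reinterpret_cast<uint16_t*>(RAW(out));
  for (R_xlen_t i = 0; i < x.size(); ++i)
    p[i] = f32_to_f16(static_cast<float>(x[i]));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fp16_unpack(RawVector r) {
  NumericVector out(r.size() / 2);
  const uint16_t* p = reinterpret_cast<const uint16_t*>(RAW(r));
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = static_cast<double>(f16_to_f32(p[i]));
  return out;
}
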