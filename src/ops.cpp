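#include <Rcpp.h>
using namespace Rcpp;

// Images passed to the SANLM filter are [H, W, C] arrays (R column-major).

// Spatial adaptive non-local means. For each pixel p, output is the
// similarity-weighted average of pixels q in the (2*search+1)^2 window,
// with w(p,q) = exp(-d2(p,q)/h^2). d2 is the mean over similarity-patch
// offsets (radius `patch`, truncated so both p+o and q+o stay in bounds)
// of the squared channel-wise difference. patch = 0 gives the pointwise
// intensity distance. Weights are shared across channels.
// [[Rcpp::export]]
NumericVector cpp_sanlm(NumericVector x, int H, int W, int C,
                        int patch, int search, double h) {
  NumericVector out((R_xlen_t)H * W * C);
  const double* px = x.begin();
  const double h2 = h * h;
  std::vector<double> acc(C);
  for (int pw = 0; pw < W; ++pw) {
    for (int ph = 0; ph < H; ++ph) {
      double wsum = 0.0;
      std::fill(acc.begin(), acc.end(), 0.0);
      const int q0h = std::max(0, ph - search), q1h = std::min(H - 1, ph + search);
      const int q0w = std::max(0, pw - search), q1w = std::min(W - 1, pw + search);
      for (int qw = q0w; qw <= q1w; ++qw) {
        for (int qh = q0h; qh <= q1h; ++qh) {
          double d2 = 0.0;
          int no = 0;
          for (int oj = -patch; oj <= patch; ++oj) {
            for (int oi = -patch; oi <= patch; ++oi) {
              const int ah = ph + oi, aw = pw + oj;
              const int bh = qh + oi, bw = qw + oj;
              if (ah < 0 || ah >= H || aw < 0 || aw >= W) continue;
              if (bh < 0 || bh >= H || bw < 0 || bw >= W) continue;
              for (int c = 0; c < C; ++c) {
                const double da = px[ah + (R_xlen_t)H * aw + (R_xlen_t)H * W * c] -
                                  px[bh + (R_xlen_t)H * bw + (R_xlen_t)H * W * c];
                d2 += da * da;
              }
              ++no;
            }
          }
          if (no > 0) d2 /= no;
          const double w = std::exp(-d2 / h2);
          wsum += w;
          for (int c = 0; c < C; ++c)
            acc[c] += w * px[qh + (R_xlen_t)H * qw + (R_xlen_t)H * W * c];
        }
      }
      for (int c = 0; c < C; ++c)
        out[ph + (R_xlen_t)H * pw + (R_xlen_t)H * W * c] = acc[c] / wsum;
    }
  }
  return out;
}

// ---- channel-last matrix layout ----------------------------------------
// Feature maps as (H*W*N) x C matrices: row index h + H*(w + W*n), one
// column per channel. This layout turns convolution, batch norm and pooling
// into plain matrix operations with no transposition.

// im2col for the channel-last layout, stored transposed: the unfolded
// matrix is (Ho*Wo*N) x (kh*kw*C [+1]) so that both the source reads and the
// destination writes run contiguously down the spatial index, and the
// convolution is cols %*% W with no transposition. When add_ones, a trailing
// all-ones column lets the bias ride inside the gemm.
// [[Rcpp::export]]
NumericMatrix cpp_im2col_nc(NumericMatrix x, int H, int W, int N,
                            int kh, int kw, int pad, int stride,
                            bool add_ones) {
  const int C = x.ncol();
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t nsp = (R_xlen_t)Ho * Wo * N;
  const int ncol = kh * kw * C + (add_ones ? 1 : 0);
  NumericMatrix cols(nsp, ncol);
  const double* px = x.begin();
  double* pc = cols.begin();
  const R_xlen_t plane = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double* dcol = pc + nsp * r;
        for (int n = 0; n < N; ++n) {
          const double* xn = px + plane * c + (R_xlen_t)H * W * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride + j - pad;
            double* dst = dcol + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            if (w < 0 || w >= W) {
              for (int ho = 0; ho < Ho; ++ho) dst[ho] = 0.0;
            } else {
              const double* src = xn + (R_xlen_t)H * w;
              for (int ho = 0; ho < Ho; ++ho) {
                const int h = ho * stride + i - pad;
                dst[ho] = (h >= 0 && h < H) ? src[h] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  if (add_ones) {
    double* dcol = pc + nsp * (ncol - 1);
    for (R_xlen_t k = 0; k < nsp; ++k) dcol[k] = 1.0;
  }
  return cols;
}

// Adjoint of cpp_im2col_nc (transposed layout, without the ones column).
// [[Rcpp::export]]
NumericMatrix cpp_col2im_nc(NumericMatrix cols, int H, int W, int N, int C,
                            int kh, int kw, int pad, int stride) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t nsp = (R_xlen_t)Ho * Wo * N;
  NumericMatrix x((R_xlen_t)H * W * N, C);
  const double* pc = cols.begin();
  double* px = x.begin();
  const R_xlen_t plane = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const double* scol = pc + nsp * r;
        for (int n = 0; n < N; ++n) {
          double* xn = px + plane * c + (R_xlen_t)H * W * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride + j - pad;
            if (w < 0 || w >= W) continue;
            const double* src = scol + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            double* dst = xn + (R_xlen_t)H * w;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride + i - pad;
              if (h >= 0 && h < H) dst[h] += src[ho];
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2 stride-2 max pooling in the channel-last layout. idx holds 1-based
// row indices into the input matrix.
// [[Rcpp::export]]
List cpp_maxpool_nc(NumericMatrix x, int H, int W, int N) {
  const int C = x.ncol();
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix out((R_xlen_t)Ho * Wo * N, C);
  IntegerMatrix idx((R_xlen_t)Ho * Wo * N, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)H * W * N * c;
    double* oc = out.begin() + (R_xlen_t)Ho * Wo * N * c;
    int* ic = idx.begin() + (R_xlen_t)Ho * Wo * N * c;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t xb = (R_xlen_t)H * W * n;
      const R_xlen_t ob = (R_xlen_t)Ho * Wo * n;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          R_xlen_t best = xb + (R_xlen_t)(2 * ho) + (R_xlen_t)H * (2 * wo);
          double bv = xc[best];
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const R_xlen_t k = xb + (2 * ho + di) + (R_xlen_t)H * (2 * wo + dj);
              if (xc[k] > bv) { bv = xc[k]; best = k; }
            }
          oc[ob + ho + (R_xlen_t)Ho * wo] = bv;
          ic[ob + ho + (R_xlen_t)Ho * wo] = (int)(best + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx,
                      _["dim"] = IntegerVector::create(Ho, Wo, N));
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd_nc(NumericMatrix dout, IntegerMatrix idx,
                                 R_xlen_t rows) {
  const int C = dout.ncol();
  NumericMatrix dx(rows, C);
  for (int c = 0; c < C; ++c) {
    const double* dc = dout.begin() + (R_xlen_t)dout.nrow() * c;
    const int* ic = idx.begin() + (R_xlen_t)idx.nrow() * c;
    double* xc = dx.begin() + rows * c;
    for (R_xlen_t k = 0; k < dout.nrow(); ++k) xc[ic[k] - 1] += dc[k];
  }
  return dx;
}

// ---- fused elementwise kernels ------------------------------------------
// Single-pass activation and batch-norm helpers; masks are logicals so the
// backward pass is one multiply.

// [[Rcpp::export]]
List cpp_relu(NumericMatrix x) {
  NumericMatrix out(x.nrow(), x.ncol());
  LogicalMatrix mask(x.nrow(), x.ncol());
  const double* px = x.begin();
  double* po = out.begin();
  int* pm = mask.begin();
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) {
    const bool pos = px[i] > 0;
    po[i] = pos ? px[i] : 0.0;
    pm[i] = pos;
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}

// [[Rcpp::export]]
List cpp_leaky(NumericMatrix x, double slope) {
  NumericMatrix out(x.nrow(), x.ncol());
  LogicalMatrix mask(x.nrow(), x.ncol());
  const double* px = x.begin();
  double* po = out.begin();
  int* pm = mask.begin();
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) {
    const bool pos = px[i] > 0;
    po[i] = pos ? px[i] : slope * px[i];
    pm[i] = pos;
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericMatrix cpp_mask_mul(NumericMatrix dout, LogicalMatrix mask, double slope) {
  NumericMatrix dx(dout.nrow(), dout.ncol());
  const double* pd = dout.begin();
  const int* pm = mask.begin();
  double* px = dx.begin();
  const R_xlen_t n = (R_xlen_t)dout.nrow() * dout.ncol();
  for (R_xlen_t i = 0; i < n; ++i) px[i] = pm[i] ? pd[i] : slope * pd[i];
  return dx;
}

// out[i,c] = x[i,c] * scale[c] + shift[c]
// [[Rcpp::export]]
NumericMatrix cpp_affine_cols(NumericMatrix x, NumericVector scale,
                              NumericVector shift) {
  const int C = x.ncol();
  const R_xlen_t n = x.nrow();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double* px = x.begin() + n * c;
    double* po = out.begin() + n * c;
    const double a = scale[c], b = shift[c];
    for (R_xlen_t i = 0; i < n; ++i) po[i] = px[i] * a + b;
  }
  return out;
}

// column means of x and x^2 in one pass
// [[Rcpp::export]]
List cpp_col_moments(NumericMatrix x) {
  const int C = x.ncol();
  const R_xlen_t n = x.nrow();
  NumericVector mu(C), m2(C);
  for (int c = 0; c < C; ++c) {
    const double* px = x.begin() + n * c;
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) { s += px[i]; s2 += px[i] * px[i]; }
    mu[c] = s / n;
    m2[c] = s2 / n;
  }
  return List::create(_["mean"] = mu, _["meansq"] = m2);
}

// training-mode batch-norm backward, fused:
// dm = ivar * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per channel
// with dxhat = dout * gamma. Also returns dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dout, NumericMatrix xhat, NumericVector gamma,
                NumericVector ivar, bool training) {
  const int C = dout.ncol();
  const R_xlen_t n = dout.nrow();
  NumericMatrix dm(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* pd = dout.begin() + n * c;
    const double* ph = xhat.begin() + n * c;
    double* po = dm.begin() + n * c;
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) { sg += pd[i] * ph[i]; sb += pd[i]; }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c], iv = ivar[c];
    if (training) {
      const double mdx = g * sb / n;          // mean of dxhat
      const double mdxx = g * sg / n;         // mean of dxhat * xhat
      for (R_xlen_t i = 0; i < n; ++i)
        po[i] = iv * (g * pd[i] - mdx - ph[i] * mdxx);
    } else {
      for (R_xlen_t i = 0; i < n; ++i) po[i] = iv * g * pd[i];
    }
  }
  return List::create(_["dm"] = dm, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
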