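// Low-level array kernels for the compute engine.
// Feature maps are dense arrays with dim c(C, H, W), column-major as in R,
// i.e. element (c,h,w) sits at c + C*h + C*H*w.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// im2col: returns (Cg*kh*kw) x (Ho*Wo) matrix for channel block [c0, c0+Cg)
static arma::mat im2col_block(const double* x, int C, int H, int W,
                              int c0, int Cg, int kh, int kw,
                              int s, int ph, int pw, int Ho, int Wo) {
  arma::mat col(Cg * kh * kw, Ho * Wo);
  col.zeros();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int pos = ho + Ho * wo;
      double* dst = col.colptr(pos);
      for (int dw = 0; dw < kw; ++dw) {
        const int wi = wo * s - pw + dw;
        for (int dh = 0; dh < kh; ++dh) {
          const int hi = ho * s - ph + dh;
          double* d = dst + Cg * (dh + kh * dw);
          if (hi < 0 || hi >= H || wi < 0 || wi >= W) continue;
          const double* src = x + c0 + C * (hi + H * wi);
          for (int c = 0; c < Cg; ++c) d[c] = src[c];
        }
      }
    }
  }
  return col;
}

// scatter-add transpose of im2col
static void col2im_block(const arma::mat& col, double* gx, int C, int H, int W,
                         int c0, int Cg, int kh, int kw,
                         int s, int ph, int pw, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int pos = ho + Ho * wo;
      const double* src = col.colptr(pos);
      for (int dw = 0; dw < kw; ++dw) {
        const int wi = wo * s - pw + dw;
        for (int dh = 0; dh < kh; ++dh) {
          const int hi = ho * s - ph + dh;
          if (hi < 0 || hi >= H || wi < 0 || wi >= W) continue;
          const double* d = src + Cg * (dh + kh * dw);
          double* dst = gx + c0 + C * (hi + H * wi);
          for (int c = 0; c < Cg; ++c) dst[c] += d[c];
        }
      }
    }
  }
}

// w is a (Co) x (Cin/g * kh * kw) matrix; columns ordered c-fastest, then kh, kw.
// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            NumericMatrix w, Nullable<NumericVector> bias,
                            int kh, int kw, int stride, int ph, int pw,
                            int groups) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  const int Co = w.nrow();
  const int Cg = C / groups, Cog = Co / groups;
  const int Ho = out_size(H, kh, stride, ph), Wo = out_size(W, kw, stride, pw);
  NumericVector out(Co * Ho * Wo);
  arma::mat wm(w.begin(), Co, w.ncol(), false);
  arma::mat om(out.begin(), Co, Ho * Wo, false, true);
  for (int g = 0; g < groups; ++g) {
    arma::mat col = im2col_block(x.begin(), C, H, W, g * Cg, Cg, kh, kw,
                                 stride, ph, pw, Ho, Wo);
    om.rows(g * Cog, (g + 1) * Cog - 1) =
      wm.rows(g * Cog, (g + 1) * Cog - 1).cols(0, Cg * kh * kw - 1) * col;
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int pos = 0; pos < Ho * Wo; ++pos)
      for (int c = 0; c < Co; ++c) out[c + Co * pos] += b[c];
  }
  out.attr("dim") = IntegerVector::create(Co, Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim,
                   NumericMatrix w, NumericVector gout,
                   int kh, int kw, int stride, int ph, int pw,
                   int groups, bool has_bias) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  const int Co = w.nrow();
  const int Cg = C / groups, Cog = Co / groups;
  const int Ho = out_size(H, kh, stride, ph), Wo = out_size(W, kw, stride, pw);
  arma::mat wm(w.begin(), Co, w.ncol(), false);
  arma::mat gm(gout.begin(), Co, Ho * Wo, false);
  NumericVector gx(C * H * W);
  NumericMatrix gw(Co, w.ncol());
  arma::mat gwm(gw.begin(), Co, w.ncol(), false, true);
  for (int g = 0; g < groups; ++g) {
    arma::mat col = im2col_block(x.begin(), C, H, W, g * Cg, Cg, kh, kw,
                                 stride, ph, pw, Ho, Wo);
    arma::mat go = gm.rows(g * Cog, (g + 1) * Cog - 1);
    gwm.rows(g * Cog, (g + 1) * Cog - 1) = go * col.t();
    arma::mat gcol = wm.rows(g * Cog, (g + 1) * Cog - 1).t() * go;
    col2im_block(gcol, gx.begin(), C, H, W, g * Cg, Cg, kh, kw,
                 stride, ph, pw, Ho, Wo);
  }
  gx.attr("dim") = xdim;
  List res = List::create(_["gx"] = gx, _["gw"] = gw);
  if (has_bias) {
    NumericVector gb(Co);
    for (int pos = 0; pos < Ho * Wo; ++pos)
      for (int c = 0; c < Co; ++c) gb[c] += gout[c + Co * pos];
    res["gb"] = gb;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xdim, int k, int stride,
                    int pad) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector out(C * Ho * Wo);
  IntegerVector arg(C * Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c) {
        double best = R_NegInf; int bi = -1;
        for (int dw = 0; dw < k; ++dw) {
          const int wi = wo * stride - pad + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            const int hi = ho * stride - pad + dh;
            if (hi < 0 || hi >= H) continue;
            const int idx = c + C * (hi + H * wi);
            if (x[idx] > best) { best = x[idx]; bi = idx; }
          }
        }
        const int o = c + C * (ho + Ho * wo);
        out[o] = best; arg[o] = bi;
      }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo);
  return List::create(_["y"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gout, IntegerVector arg,
                             IntegerVector xdim) {
  NumericVector gx(xdim[0] * xdim[1] * xdim[2]);
  for (int i = 0; i < gout.size(); ++i)
    if (arg[i] >= 0) gx[arg[i]] += gout[i];
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  NumericVector out(C * 2 * H * 2 * W);
  const int Ho = 2 * H;
  for (int wo = 0; wo < 2 * W; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = &x[0] + C * ((ho / 2) + H * (wo / 2));
      double* dst = &out[0] + C * (ho + Ho * wo);
      for (int c = 0; c < C; ++c) dst[c] = src[c];
    }
  out.attr("dim") = IntegerVector::create(C, Ho, 2 * W);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector gout, IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  NumericVector gx(C * H * W);
  const int Ho = 2 * H;
  for (int wo = 0; wo < 2 * W; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = &gout[0] + C * (ho + Ho * wo);
      double* dst = &gx[0] + C * ((ho / 2) + H * (wo / 2));
      for (int c = 0; c < C; ++c) dst[c] += src[c];
    }
  gx.attr("dim") = xdim;
  return gx;
}
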