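#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as R arrays with dim = c(C, H, W): element (c, h, w)
// (0-based) lives at index c + C*h + C*H*w.  All spatial coordinates are
// 0-based (row, col) in continuous space; reads outside [0,H-1]x[0,W-1]
// contribute zero (zero padding), matching the finite support of the
// bilinear kernel g(a,b) = max(0, 1 - |a-b|).

static inline int idx3(int c, int h, int w, int C, int H) {
  return c + C * (h + H * w);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  const int O = wdim[0], KH = wdim[2], KW = wdim[3];
  const int ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  NumericVector y(O * H * W);
  for (int wo = 0; wo < W; ++wo) {
    for (int ho = 0; ho < H; ++ho) {
      for (int o = 0; o < O; ++o) {
        double acc = b[o];
        for (int kw = 0; kw < KW; ++kw) {
          int wi = wo + kw - pw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            int hi = ho + kh - ph;
            if (hi < 0 || hi >= H) continue;
            for (int c = 0; c < C; ++c) {
              // w[o, c, kh, kw]
              acc += w[o + O * (c + C * (kh + KH * kw))] * x[idx3(c, hi, wi, C, H)];
            }
          }
        }
        y[idx3(o, ho, wo, O, H)] = acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(O, H, W);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gy) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  const int O = wdim[0], KH = wdim[2], KW = wdim[3];
  const int ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  NumericVector gx(C * H * W), gw(O * C * KH * KW), gb(O);
  for (int wo = 0; wo < W; ++wo) {
    for (int ho = 0; ho < H; ++ho) {
      for (int o = 0; o < O; ++o) {
        double g = gy[idx3(o, ho, wo, O, H)];
        if (g == 0.0) continue;
        gb[o] += g;
        for (int kw = 0; kw < KW; ++kw) {
          int wi = wo + kw - pw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            int hi = ho + kh - ph;
            if (hi < 0 || hi >= H) continue;
            for (int c = 0; c < C; ++c) {
              int wi_idx = o + O * (c + C * (kh + KH * kw));
              int xi_idx = idx3(c, hi, wi, C, H);
              gx[xi_idx] += g * w[wi_idx];
              gw[wi_idx] += g * x[xi_idx];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Bilinear gather: sample every channel of x at M fractional positions
// (pr[m], pc[m]); returns a [C, M] matrix.  Out-of-range corners contribute 0.
// [[Rcpp::export]]
NumericVector cpp_bl_gather_fwd(NumericVector x, IntegerVector xdim,
                                NumericVector pr, NumericVector pc) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  const int M = pr.size();
  NumericVector y(C * M);
  for (int m = 0; m < M; ++m) {
    double r = pr[m], c = pc[m];
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    double ar = r - r0, ac = c - c0;
    for (int dr = 0; dr <= 1; ++dr) {
      int ri = r0 + dr;
      if (ri < 0 || ri >= H) continue;
      double wr = dr ? ar : 1.0 - ar;
      if (wr == 0.0) continue;
      for (int dc = 0; dc <= 1; ++dc) {
        int ci = c0 + dc;
        if (ci < 0 || ci >= W) continue;
        double wv = wr * (dc ? ac : 1.0 - ac);
        if (wv == 0.0) continue;
        for (int ch = 0; ch < C; ++ch)
          y[ch + C * m] += wv * x[idx3(ch, ri, ci, C, H)];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, M);
  return y;
}

// Backward of the bilinear gather w.r.t. the map and the positions.
// Position gradients are summed over channels; at integer coordinates the
// one-sided derivative of the hat kernel is used (subgradient choice).
// [[Rcpp::export]]
List cpp_bl_gather_bwd(NumericVector x, IntegerVector xdim,
                       NumericVector pr, NumericVector pc,
                       NumericVector gy) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  const int M = pr.size();
  NumericVector gx(C * H * W), gpr(M), gpc(M);
  for (int m = 0; m < M; ++m) {
    double r = pr[m], c = pc[m];
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    double ar = r - r0, ac = c - c0;
    for (int dr = 0; dr <= 1; ++dr) {
      int ri = r0 + dr;
      if (ri < 0 || ri >= H) continue;
      double wr = dr ? ar : 1.0 - ar;
      double dwr = dr ? 1.0 : -1.0;
      for (int dc = 0; dc <= 1; ++dc) {
        int ci = c0 + dc;
        if (ci < 0 || ci >= W) continue;
        double wc = dc ? ac : 1.0 - ac;
        double dwc = dc ? 1.0 : -1.0;
        for (int ch = 0; ch < C; ++ch) {
          double g = gy[ch + C * m];
          if (g == 0.0) continue;
          double xv = x[idx3(ch, ri, ci, C, H)];
          gx[idx3(ch, ri, ci, C, H)] += g * wr * wc;
          gpr[m] += g * dwr * wc * xv;
          gpc[m] += g * wr * dwc * xv;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gpr"] = gpr, _["gpc"] = gpc);
}

// 2x2 max pooling, stride 2.  Returns pooled values and the (1-based) linear
// argmax index into x for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(C * Ho * Wo);
  IntegerVector amax(C * Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int c = 0; c < C; ++c) {
        double best = R_NegInf; int besti = -1;
        for (int dw = 0; dw <= 1; ++dw) {
          for (int dh = 0; dh <= 1; ++dh) {
            int i = idx3(c, 2 * ho + dh, 2 * wo + dw, C, H);
            if (x[i] > best) { best = x[i]; besti = i; }
          }
        }
        int oi = idx3(c, ho, wo, C, Ho);
        y[oi] = best;
        amax[oi] = besti + 1;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo);
  return List::create(_["y"] = y, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector amax, NumericVector gy,
                               IntegerVector xdim) {
  NumericVector gx(xdim[0] * xdim[1] * xdim[2]);
  for (int i = 0; i < amax.size(); ++i) gx[amax[i] - 1] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}
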