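#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Feature maps are R arrays dim (H, W, C), column-major.
// im2col layout: cols is (H*W x 9C); row = h + H*w, column = c*9 +
// (kw+1)*3 + (kh+1). Columns are contiguous in memory, so both the fill
// loop and the GEMM read/write sequentially.

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, int H, int W, int C) {
  const int hw = H * W;
  NumericMatrix out(hw, 9 * C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* ch = px + (size_t)c * hw;
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        int r = c * 9 + (kw + 1) * 3 + (kh + 1);
        double* col = po + (size_t)r * hw;
        for (int w = 0; w < W; ++w) {
          int ws = w + kw;
          double* dst = col + (size_t)H * w;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = ch + (size_t)H * ws;
          if (kh == 0) {
            std::copy(src, src + H, dst);
          } else if (kh == -1) {
            dst[0] = 0.0;
            std::copy(src, src + H - 1, dst + 1);
          } else {
            std::copy(src + 1, src + H, dst);
            dst[H - 1] = 0.0;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add column gradients back to the input grid.
// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix cols, int H, int W, int C) {
  const int hw = H * W;
  NumericVector dx(hw * C);
  double* pdx = dx.begin();
  const double* pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    double* ch = pdx + (size_t)c * hw;
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        int r = c * 9 + (kw + 1) * 3 + (kh + 1);
        const double* col = pc + (size_t)r * hw;
        for (int w = 0; w < W; ++w) {
          int ws = w + kw;
          if (ws < 0 || ws >= W) continue;
          double* dst = ch + (size_t)H * ws;
          const double* src = col + (size_t)H * w;
          if (kh == 0) {
            for (int h = 0; h < H; ++h) dst[h] += src[h];
          } else if (kh == -1) {
            for (int h = 1; h < H; ++h) dst[h - 1] += src[h];
          } else {
            for (int h = 0; h < H - 1; ++h) dst[h + 1] += src[h];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// 2x2 max pooling, stride 2; H and W must be even.
// Returns pooled values and 1-based linear argmax indices into x.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    size_t off = (size_t)c * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double best = -1e300; int bi = -1;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            int li = (2 * h + dh) + H * (2 * w + dw);
            double v = px[off + li];
            if (v > best) { best = v; bi = li; }
          }
        }
        size_t oi = (size_t)c * Ho * Wo + h + Ho * w;
        out[oi] = best;
        idx[oi] = (int)(off + bi) + 1;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dout, IntegerVector idx,
                               int H, int W, int C) {
  NumericVector dx(H * W * C);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[idx[i] - 1] += dout[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

static inline void bilin_coef(int i, int n_src, int& i0, int& i1, double& f) {
  double s = (i + 0.5) / 2.0 - 0.5;
  double fl = std::floor(s);
  i0 = (int)fl; i1 = i0 + 1; f = s - fl;
  if (i0 < 0) i0 = 0;
  if (i1 > n_src - 1) i1 = n_src - 1;
}

// Bilinear x2 upsampling (align_corners = false), per channel.
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x, int H, int W, int C) {
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out(Ho * Wo * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* ch = px + (size_t)c * H * W;
    double* oc = out.begin() + (size_t)c * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      int w0, w1; double fw;
      bilin_coef(w, W, w0, w1, fw);
      for (int h = 0; h < Ho; ++h) {
        int h0, h1; double fh;
        bilin_coef(h, H, h0, h1, fh);
        oc[h + Ho * w] =
          (1 - fh) * (1 - fw) * ch[h0 + H * w0] +
          fh * (1 - fw) * ch[h1 + H * w0] +
          (1 - fh) * fw * ch[h0 + H * w1] +
          fh * fw * ch[h1 + H * w1];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector dout, int H, int W, int C) {
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(H * W * C);
  const double* pd = dout.begin();
  for (int c = 0; c < C; ++c) {
    double* ch = dx.begin() + (size_t)c * H * W;
    const double* oc = pd + (size_t)c * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      int w0, w1; double fw;
      bilin_coef(w, W, w0, w1, fw);
      for (int h = 0; h < Ho; ++h) {
        int h0, h1; double fh;
        bilin_coef(h, H, h0, h1, fh);
        double g = oc[h + Ho * w];
        ch[h0 + H * w0] += (1 - fh) * (1 - fw) * g;
        ch[h1 + H * w0] += fh * (1 - fw) * g;
        ch[h0 + H * w1] += (1 - fh) * fw * g;
        ch[h1 + H * w1] += fh * fw * g;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// 6-connected component labelling of a binary 3-D mask (dim H, W, L).
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, int H, int W, int L) {
  IntegerVector lab(mask.size());
  lab.attr("dim") = IntegerVector::create(H, W, L);
  int next = 0;
  std::queue<int> q;
  const int n = H * W * L;
  for (int s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int h = v % H, w = (v / H) % W, l = v / (H * W);
      const int dh[6] = {-1, 1, 0, 0, 0, 0};
      const int dw[6] = {0, 0, -1, 1, 0, 0};
      const int dl[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int hh = h + dh[k], ww = w + dw[k], ll = l + dl[k];
        if (hh < 0 || hh >= H || ww < 0 || ww >= W || ll < 0 || ll >= L) continue;
        int u = hh + H * (ww + W * ll);
        if (mask[u] != 0 && lab[u] == 0) { lab[u] = next; q.push(u); }
      }
    }
  }
  return lab;
}

// 1-based (h, w, l) indices of foreground voxels with a face-adjacent
// background neighbour or lying on the array boundary.
// [[Rcpp::export]]
IntegerMatrix surface_voxels_cpp(IntegerVector mask, int H, int W, int L) {
  std::vector<int> hh, ww, ll;
  for (int l = 0; l < L; ++l) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        if (mask[h + H * (w + W * l)] == 0) continue;
        bool surf = h == 0 || h == H - 1 || w == 0 || w == W - 1 ||
                    l == 0 || l == L - 1;
        if (!surf) {
          surf = mask[(h - 1) + H * (w + W * l)] == 0 ||
                 mask[(h + 1) + H * (w + W * l)] == 0 ||
                 mask[h + H * ((w - 1) + W * l)] == 0 ||
                 mask[h + H * ((w + 1) + W * l)] == 0 ||
                 mask[h + H * (w + W * (l - 1))] == 0 ||
                 mask[h + H * (w + W * (l + 1))] == 0;
        }
        if (surf) { hh.push_back(h + 1); ww.push_back(w + 1); ll.push_back(l + 1); }
      }
    }
  }
  IntegerMatrix out(hh.size(), 3);
  for (size_t i = 0; i < hh.size(); ++i) {
    out(i, 0) = hh[i]; out(i, 1) = ww[i]; out(i, 2) = ll[i];
  }
  return out;
}

// For each row of A (n x 3, mm), the Euclidean distance to its nearest
// neighbour among the rows of B.
// [[Rcpp::export]]
NumericVector nn_dists_cpp(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double a0 = A(i, 0), a1 = A(i, 1), a2 = A(i, 2);
    for (int j = 0; j < m; ++j) {
      double d0 = a0 - B(j, 0), d1 = a1 - B(j, 1), d2 = a2 - B(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
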