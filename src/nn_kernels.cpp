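// Inner loops of the neural-network engine. Tensors are R arrays with
// dim = c(H, W, C, N) (column-major), weights dim = c(k, k, Cin, Cout).
#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Unfold k x k patches so a standard convolution becomes a matrix product:
// rows ordered (ho fastest, then wo, then n); columns ki + k*kj + k*k*c,
// matching the native flattening of a (k, k, Cin, Cout) weight array.
// [[Rcpp::export]]
NumericMatrix nn_im2col(const NumericVector& x, int H, int W, int C, int N,
                        int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out((R_xlen_t)N * Ho * Wo, (R_xlen_t)k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t nrow = (R_xlen_t)N * Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const R_xlen_t col = (R_xlen_t)c * k * k + (R_xlen_t)kj * k + ki;
        double* ocol = op + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xin = xp + ((R_xlen_t)n * C + c) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            R_xlen_t r = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho;
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) ocol[r + ho] = 0.0;
              continue;
            }
            const double* xcolv = xin + (R_xlen_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              ocol[r + ho] = (hi < 0 || hi >= H) ? 0.0 : xcolv[hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of nn_im2col (gradient w.r.t. the convolution input).
// [[Rcpp::export]]
NumericVector nn_col2im(const NumericMatrix& cols, int H, int W, int C, int N,
                        int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)N * Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const R_xlen_t col = (R_xlen_t)c * k * k + (R_xlen_t)kj * k + ki;
        const double* ccol = cp + col * nrow;
        for (int n = 0; n < N; ++n) {
          double* xin = xp + ((R_xlen_t)n * C + c) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            double* xcolv = xin + (R_xlen_t)wi * H;
            R_xlen_t r = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi >= 0 && hi < H) xcolv[hi] += ccol[r + ho];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Depthwise 3x3/5x5 convolution: one spatial filter per channel.
// w has dim c(k, k, C).
// [[Rcpp::export]]
NumericVector nn_dwconv_fw(const NumericVector& x, const NumericVector& w,
                           int H, int W, int C, int N, int k, int stride) {
  const int pad = (k - 1) / 2;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xin = xp + ((R_xlen_t)n * C + c) * H * W;
      const double* wc = wp + (R_xlen_t)c * k * k;
      double* oc = op + ((R_xlen_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              acc += xin[(R_xlen_t)wi * H + hi] * wc[kj * k + ki];
            }
          }
          oc[(R_xlen_t)wo * Ho + ho] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
List nn_dwconv_bw(const NumericVector& x, const NumericVector& w,
                  const NumericVector& gout, int H, int W, int C, int N,
                  int k, int stride) {
  const int pad = (k - 1) / 2;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector gx((R_xlen_t)H * W * C * N);
  NumericVector gw((R_xlen_t)k * k * C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xin = xp + ((R_xlen_t)n * C + c) * H * W;
      const double* wc = wp + (R_xlen_t)c * k * k;
      const double* gc = gp + ((R_xlen_t)n * C + c) * Ho * Wo;
      double* gxc = gxp + ((R_xlen_t)n * C + c) * H * W;
      double* gwc = gwp + (R_xlen_t)c * k * k;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gc[(R_xlen_t)wo * Ho + ho];
          if (g == 0.0) continue;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              gxc[(R_xlen_t)wi * H + hi] += wc[kj * k + ki] * g;
              gwc[kj * k + ki] += xin[(R_xlen_t)wi * H + hi] * g;
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  gw.attr("dim") = IntegerVector::create(k, k, C);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// 2x2 max pooling with stride 2; records flat argmax indices for backprop.
// [[Rcpp::export]]
List nn_maxpool2_fw(const NumericVector& x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t xoff = ((R_xlen_t)n * C + c) * H * W;
      const R_xlen_t ooff = ((R_xlen_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          R_xlen_t bidx = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const R_xlen_t pos = xoff + (R_xlen_t)(2 * wo + dj) * H + 2 * ho + di;
              if (xp[pos] > best) { best = xp[pos]; bidx = pos; }
            }
          }
          op[ooff + (R_xlen_t)wo * Ho + ho] = best;
          ip[ooff + (R_xlen_t)wo * Ho + ho] = (int)bidx;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_bw(const IntegerVector& idx, const NumericVector& gout,
                             int H, int W, int C, int N) {
  NumericVector gx((R_xlen_t)H * W * C * N);
  double* gp = gx.begin();
  const double* go = gout.begin();
  const int* ip = idx.begin();
  const R_xlen_t m = gout.size();
  for (R_xlen_t i = 0; i < m; ++i) gp[ip[i]] += go[i];
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// 8-connected components of a binary mask via union-find; labels are
// 1..n_components in raster order of first appearance, 0 = background.
// [[Rcpp::export]]
IntegerMatrix nn_label_components(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> parent(1, 0);
  IntegerMatrix lab(H, W);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0) continue;
      int best = 0;
      // neighbours already visited in column-major raster order
      const int di[4] = {-1, -1, 0, 1};
      const int dj[4] = {0, -1, -1, -1};
      for (int t = 0; t < 4; ++t) {
        const int ii = i + di[t], jj = j + dj[t];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        const int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l; else unite(best, l);
        }
      }
      if (best == 0) {
        parent.push_back(next);
        best = next++;
      }
      lab(i, j) = best;
    }
  }
  // flatten and renumber in order of first appearance
  std::vector<int> remap(next, 0);
  int out_next = 1;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (lab(i, j) == 0) continue;
      const int r = find(lab(i, j));
      if (remap[r] == 0) remap[r] = out_next++;
      lab(i, j) = remap[r];
    }
  }
  return lab;
}
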