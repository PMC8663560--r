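// Low-level volumetric kernels: 3D convolution via im2col + GEMM, pooling,
// connected-component labelling, separable Gaussian blur and trilinear
// sampling.  All voxel grids are passed as flat numeric vectors in R's
// column-major order with dims (D, H, W[, C[, B]]) where D is the vertical
// (slice) axis.

#include <RcppArmadillo.h>
#include <queue>

using namespace Rcpp;

// Fill the im2col patch matrix P (V x k^3*Cin) for one sample.
// Column layout matches the column-major flattening of an R array with
// dims (k, k, k, Cin): col = ((c*k + ow)*k + oh)*k + od.
static void im2col3d(const double* x, int D, int H, int W, int Cin,
                     int k, int pad, arma::mat& P) {
  const int V = D * H * W;
  P.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (std::size_t)V * c;
    for (int ow = 0; ow < k; ++ow) {
      for (int oh = 0; oh < k; ++oh) {
        for (int od = 0; od < k; ++od) {
          const int col = ((c * k + ow) * k + oh) * k + od;
          double* Pcol = P.colptr(col);
          for (int w = 0; w < W; ++w) {
            const int ws = w + ow - pad;
            if (ws < 0 || ws >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int hs = h + oh - pad;
              if (hs < 0 || hs >= H) continue;
              const int d0 = std::max(0, pad - od);
              const int d1 = std::min(D, D + pad - od);
              const std::size_t src_base = (std::size_t)(ws * H + hs) * D;
              const std::size_t dst_base = (std::size_t)(w * H + h) * D;
              for (int d = d0; d < d1; ++d) {
                Pcol[dst_base + d] = xc[src_base + d + od - pad];
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add of the patch-gradient matrix back onto the input grid.
static void col2im3d(const arma::mat& dP, int D, int H, int W, int Cin,
                     int k, int pad, double* dx) {
  const int V = D * H * W;
  for (int c = 0; c < Cin; ++c) {
    double* dxc = dx + (std::size_t)V * c;
    for (int ow = 0; ow < k; ++ow) {
      for (int oh = 0; oh < k; ++oh) {
        for (int od = 0; od < k; ++od) {
          const int col = ((c * k + ow) * k + oh) * k + od;
          const double* Pcol = dP.colptr(col);
          for (int w = 0; w < W; ++w) {
            const int ws = w + ow - pad;
            if (ws < 0 || ws >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int hs = h + oh - pad;
              if (hs < 0 || hs >= H) continue;
              const int d0 = std::max(0, pad - od);
              const int d1 = std::min(D, D + pad - od);
              const std::size_t src_base = (std::size_t)(ws * H + hs) * D;
              const std::size_t dst_base = (std::size_t)(w * H + h) * D;
              for (int d = d0; d < d1; ++d) {
                dxc[src_base + d + od - pad] += Pcol[dst_base + d];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, NumericMatrix w,
                                 NumericVector bias, IntegerVector dims,
                                 int cin, int nb, int k, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int V = D * H * W;
  const int cout = w.ncol();
  const arma::mat Wm(const_cast<double*>(w.begin()), w.nrow(), cout, false);
  const arma::rowvec bm(const_cast<double*>(bias.begin()), cout, false);
  NumericVector out((std::size_t)V * cout * nb);
  arma::mat P(V, k * k * k * cin);
  for (int b = 0; b < nb; ++b) {
    im2col3d(x.begin() + (std::size_t)V * cin * b, D, H, W, cin, k, pad, P);
    arma::mat Y = P * Wm;
    Y.each_row() += bm;
    std::copy(Y.begin(), Y.end(), out.begin() + (std::size_t)V * cout * b);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                         IntegerVector dims, int cin, int nb, int k, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int V = D * H * W;
  const int cout = w.ncol();
  const arma::mat Wm(const_cast<double*>(w.begin()), w.nrow(), cout, false);
  NumericVector dx((std::size_t)V * cin * nb);
  arma::mat dW(w.nrow(), cout, arma::fill::zeros);
  arma::rowvec db(cout, arma::fill::zeros);
  arma::mat P(V, k * k * k * cin);
  for (int b = 0; b < nb; ++b) {
    im2col3d(x.begin() + (std::size_t)V * cin * b, D, H, W, cin, k, pad, P);
    const arma::mat dY(const_cast<double*>(dy.begin()) + (std::size_t)V * cout * b,
                       V, cout, false);
    dW += P.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dP = dY * Wm.t();
    col2im3d(dP, D, H, W, cin, k, pad, dx.begin() + (std::size_t)V * cin * b);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(w.nrow(), cout, dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

static inline int ceil_div2(int n) { return (n + 1) / 2; }

// Max pooling, window 2, stride 2, ceil mode.  Returns pooled values and the
// 0-based argmax voxel index (within a single channel plane) for backward.
// [[Rcpp::export]]
List cpp_maxpool3d_forward(NumericVector x, IntegerVector dims, int nc, int nb) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int V = D * H * W;
  const int Do = ceil_div2(D), Ho = ceil_div2(H), Wo = ceil_div2(W);
  const int Vo = Do * Ho * Wo;
  NumericVector y((std::size_t)Vo * nc * nb);
  IntegerVector idx((std::size_t)Vo * nc * nb);
  for (int bc = 0; bc < nb * nc; ++bc) {
    const double* xp = x.begin() + (std::size_t)V * bc;
    double* yp = y.begin() + (std::size_t)Vo * bc;
    int* ip = idx.begin() + (std::size_t)Vo * bc;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        for (int d = 0; d < Do; ++d) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int dw = 0; dw < 2; ++dw) {
            const int ws = 2 * w + dw; if (ws >= W) continue;
            for (int dh = 0; dh < 2; ++dh) {
              const int hs = 2 * h + dh; if (hs >= H) continue;
              for (int dd = 0; dd < 2; ++dd) {
                const int ds = 2 * d + dd; if (ds >= D) continue;
                const int src = ds + D * (hs + H * ws);
                if (xp[src] > best) { best = xp[src]; besti = src; }
              }
            }
          }
          const int dst = d + Do * (h + Ho * w);
          yp[dst] = best;
          ip[dst] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_backward(NumericVector dy, IntegerVector idx,
                                     IntegerVector dims, int nc, int nb) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int V = D * H * W;
  const int Vo = ceil_div2(D) * ceil_div2(H) * ceil_div2(W);
  NumericVector dx((std::size_t)V * nc * nb);
  for (int bc = 0; bc < nb * nc; ++bc) {
    const double* dyp = dy.begin() + (std::size_t)Vo * bc;
    const int* ip = idx.begin() + (std::size_t)Vo * bc;
    double* dxp = dx.begin() + (std::size_t)V * bc;
    for (int v = 0; v < Vo; ++v) dxp[ip[v]] += dyp[v];
  }
  return dx;
}

// Average pooling, window 2, stride 2, ceil mode; divisor is the number of
// in-bounds voxels in each window.
// [[Rcpp::export]]
NumericVector cpp_avgpool3d_forward(NumericVector x, IntegerVector dims,
                                    int nc, int nb) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int V = D * H * W;
  const int Do = ceil_div2(D), Ho = ceil_div2(H), Wo = ceil_div2(W);
  const int Vo = Do * Ho * Wo;
  NumericVector y((std::size_t)Vo * nc * nb);
  for (int bc = 0; bc < nb * nc; ++bc) {
    const double* xp = x.begin() + (std::size_t)V * bc;
    double* yp = y.begin() + (std::size_t)Vo * bc;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        for (int d = 0; d < Do; ++d) {
          double acc = 0; int cnt = 0;
          for (int dw = 0; dw < 2; ++dw) {
            const int ws = 2 * w + dw; if (ws >= W) continue;
            for (int dh = 0; dh < 2; ++dh) {
              const int hs = 2 * h + dh; if (hs >= H) continue;
              for (int dd = 0; dd < 2; ++dd) {
                const int ds = 2 * d + dd; if (ds >= D) continue;
                acc += xp[ds + D * (hs + H * ws)];
                ++cnt;
              }
            }
          }
          yp[d + Do * (h + Ho * w)] = acc / cnt;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool3d_backward(NumericVector dy, IntegerVector dims,
                                     int nc, int nb) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int V = D * H * W;
  const int Do = ceil_div2(D), Ho = ceil_div2(H), Wo = ceil_div2(W);
  const int Vo = Do * Ho * Wo;
  NumericVector dx((std::size_t)V * nc * nb);
  for (int bc = 0; bc < nb * nc; ++bc) {
    const double* dyp = dy.begin() + (std::size_t)Vo * bc;
    double* dxp = dx.begin() + (std::size_t)V * bc;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        for (int d = 0; d < Do; ++d) {
          int cnt = 0;
          for (int dw = 0; dw < 2; ++dw) {
            const int ws = 2 * w + dw; if (ws >= W) continue;
            for (int dh = 0; dh < 2; ++dh) {
              const int hs = 2 * h + dh; if (hs >= H) continue;
              for (int dd = 0; dd < 2; ++dd) {
                const int ds = 2 * d + dd; if (ds >= D) continue;
                ++cnt;
              }
            }
          }
          const double g = dyp[d + Do * (h + Ho * w)] / cnt;
          for (int dw = 0; dw < 2; ++dw) {
            const int ws = 2 * w + dw; if (ws >= W) continue;
            for (int dh = 0; dh < 2; ++dh) {
              const int hs = 2 * h + dh; if (hs >= H) continue;
              for (int dd = 0; dd < 2; ++dd) {
                const int ds = 2 * d + dd; if (ds >= D) continue;
                dxp[ds + D * (hs + H * ws)] += g;
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// 6-connected component labelling of a binary 3D mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int V = D * H * W;
  IntegerVector lab(V, 0);
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < V; ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      const int v = q.front(); q.pop();
      const int d = v % D, h = (v / D) % H, w = v / (D * H);
      const int nd[6] = {d - 1, d + 1, d, d, d, d};
      const int nh[6] = {h, h, h - 1, h + 1, h, h};
      const int nw[6] = {w, w, w, w, w - 1, w + 1};
      for (int i = 0; i < 6; ++i) {
        if (nd[i] < 0 || nd[i] >= D || nh[i] < 0 || nh[i] >= H ||
            nw[i] < 0 || nw[i] >= W) continue;
        const int u = nd[i] + D * (nh[i] + H * nw[i]);
        if (mask[u] && !lab[u]) { lab[u] = next; q.push(u); }
      }
    }
  }
  return lab;
}

// Separable Gaussian blur with reflected boundaries.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector x, IntegerVector dims,
                                  double sigma) {
  const int D = dims[0], H = dims[1], W = dims[2];
  if (sigma <= 0) return clone(x);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (double& v : ker) v /= s;
  NumericVector a = clone(x), b(x.size());
  const int n[3] = {D, H, W};
  const int stride[3] = {1, D, D * H};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = n[ax], st = stride[ax];
    const int nlines = (D * H * W) / len;
    for (int line = 0; line < nlines; ++line) {
      // decompose the line index into the two fixed coordinates
      int base = 0, rem = line;
      for (int oth = 0; oth < 3; ++oth) {
        if (oth == ax) continue;
        base += (rem % n[oth]) * stride[oth];
        rem /= n[oth];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int o = -r; o <= r; ++o) {
          int j = i + o;
          if (j < 0) j = -j - 1;
          if (j >= len) j = 2 * len - j - 1;
          j = std::min(std::max(j, 0), len - 1);
          acc += ker[o + r] * a[base + j * st];
        }
        b[base + i * st] = acc;
      }
    }
    std::swap(a, b);
  }
  return a;
}

// Trilinear sampling at arbitrary (possibly fractional) 1-based coordinates;
// out-of-grid samples return 0.
// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector x, IntegerVector dims,
                                   NumericMatrix coords) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int n = coords.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double cd = coords(i, 0) - 1.0, ch = coords(i, 1) - 1.0,
                 cw = coords(i, 2) - 1.0;
    if (cd < 0 || ch < 0 || cw < 0 || cd > D - 1 || ch > H - 1 || cw > W - 1) {
      out[i] = 0.0;
      continue;
    }
    const int d0 = std::min((int)std::floor(cd), D - 1);
    const int h0 = std::min((int)std::floor(ch), H - 1);
    const int w0 = std::min((int)std::floor(cw), W - 1);
    const int d1 = std::min(d0 + 1, D - 1);
    const int h1 = std::min(h0 + 1, H - 1);
    const int w1 = std::min(w0 + 1, W - 1);
    const double fd = cd - d0, fh = ch - h0, fw = cw - w0;
    double acc = 0;
    const int ds[2] = {d0, d1}; const double wd[2] = {1 - fd, fd};
    const int hs[2] = {h0, h1}; const double wh[2] = {1 - fh, fh};
    const int wsx[2] = {w0, w1}; const double ww[2] = {1 - fw, fw};
    for (int a = 0; a < 2; ++a)
      for (int bq = 0; bq < 2; ++bq)
        for (int c = 0; c < 2; ++c)
          acc += wd[a] * wh[bq] * ww[c] *
                 x[ds[a] + D * (hs[bq] + H * wsx[c])];
    out[i] = acc;
  }
  return out;
}
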