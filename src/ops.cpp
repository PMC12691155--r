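#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// symmetric reflection with edge duplication: (c b a | a b c | c b a)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& g, int k) {
  const int H = g.nrow(), W = g.ncol(), p = k / 2, k2 = k * k;
  NumericMatrix out(H, W);
  std::vector<double> buf(k2);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      int m = 0;
      for (int dw = -p; dw <= p; ++dw) {
        const int wi = reflect_idx(w + dw, W);
        for (int dh = -p; dh <= p; ++dh)
          buf[m++] = g(reflect_idx(h + dh, H), wi);
      }
      std::nth_element(buf.begin(), buf.begin() + k2 / 2, buf.end());
      out(h, w) = buf[k2 / 2];
    }
  }
  return out;
}

// 8-connected component labeling; labels assigned in raster-scan
// discovery order (column-major, matching R's storage).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w) != 0) continue;
      ++next;
      lab(h, w) = next;
      stack.push_back(h + H * w);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ch = idx % H, cw = idx / H;
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            const int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              stack.push_back(nh + H * nw);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Feature maps are matrices of (H*W*N) rows x C cols, row index
// r = h + H*w + H*W*n (0-based).  im2col unfolds k x k patches so a
// convolution becomes cols %*% Wmat with Wmat of (C*k*k) x Cout and
// row index c + C*(kh + k*kw).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int N,
                         int C, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo * N, C * k * k);
  for (int kw = 0; kw < k; ++kw) {
    for (int kh = 0; kh < k; ++kh) {
      for (int c = 0; c < C; ++c) {
        const int j = c + C * (kh + k * kw);
        double* oc = &out(0, j);
        const double* xc = &x(0, c);
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            const int ro0 = Ho * (wo + Wo * n);
            if (wi < 0 || wi >= W) continue; // zero padding
            const int ri0 = H * (wi + W * n);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + kh - pad;
              if (hi < 0 || hi >= H) continue;
              oc[ro0 + ho] = xc[ri0 + hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcols, int H, int W, int N,
                         int C, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix dx(H * W * N, C);
  for (int kw = 0; kw < k; ++kw) {
    for (int kh = 0; kh < k; ++kh) {
      for (int c = 0; c < C; ++c) {
        const int j = c + C * (kh + k * kw);
        const double* dc = &dcols(0, j);
        double* xc = &dx(0, c);
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            const int ro0 = Ho * (wo + Wo * n);
            const int ri0 = H * (wi + W * n);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + kh - pad;
              if (hi < 0 || hi >= H) continue;
              xc[ri0 + hi] += dc[ro0 + ho];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling with -inf padding; argmax returns 1-based source rows so
// the backward pass can scatter gradients with R matrix indexing.
// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& x, int H, int W, int N, int C,
                 int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix y(Ho * Wo * N, C);
  IntegerMatrix arg(Ho * Wo * N, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int bestr = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * stride + kh - pad;
              if (hi < 0 || hi >= H) continue;
              const int r = hi + H * (wi + W * n);
              if (xc[r] > best) { best = xc[r]; bestr = r; }
            }
          }
          const int ro = ho + Ho * (wo + Wo * n);
          y(ro, c) = best;
          arg(ro, c) = bestr + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dy,
                              const IntegerMatrix& arg, int nrow_x) {
  const int R = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(nrow_x, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r)
      dx(arg(r, c) - 1, c) += dy(r, c);
  return dx;
}

// Row-wise max and (first) argmax over columns; used by the channel-max
// pooling branch of spatial attention.
// [[Rcpp::export]]
List cpp_row_max(const NumericMatrix& x) {
  const int R = x.nrow(), C = x.ncol();
  NumericVector m(R);
  IntegerVector a(R);
  for (int r = 0; r < R; ++r) { m[r] = x(r, 0); a[r] = 1; }
  for (int c = 1; c < C; ++c)
    for (int r = 0; r < R; ++r)
      if (x(r, c) > m[r]) { m[r] = x(r, c); a[r] = c + 1; }
  return List::create(_["max"] = m, _["argmax"] = a);
}
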