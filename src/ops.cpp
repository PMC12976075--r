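#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// All image buffers are R arrays in [H, W, C] layout (column-major:
// index = h + H*(w + W*c)), pixel (h, w) = (row/y, col/x).

// 3x3 convolution, stride 1, zero padding 1 ("same").
// x: [H,W,Cin], w: [3,3,Cin,Cout] (kh fastest), b: [Cout] -> y: [H,W,Cout]
// [[Rcpp::export]]
NumericVector cpp_conv3_fw(NumericVector x, NumericVector w, NumericVector b,
                           int H, int W, int Cin, int Cout,
                           bool relu = false) {
  NumericVector y((R_xlen_t)H * W * Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    const double bias = b[co];
    for (int wc = 0; wc < W; ++wc) {
      double* ycol = yp + (R_xlen_t)H * (wc + (R_xlen_t)W * co);
      for (int h = 0; h < H; ++h) ycol[h] = bias;
      for (int ci = 0; ci < Cin; ++ci) {
        for (int kw = 0; kw < 3; ++kw) {
          const int ws = wc + kw - 1;
          if (ws < 0 || ws >= W) continue;
          const double* xcol = xp + (R_xlen_t)H * (ws + (R_xlen_t)W * ci);
          const double* wk = wp + 3 * (kw + 3 * (ci + (R_xlen_t)Cin * co));
          const double w0 = wk[0], w1 = wk[1], w2 = wk[2];
          if (H == 1) { ycol[0] += w1 * xcol[0]; continue; }
          // single fused pass over the column; borders handled separately
          ycol[0] += w1 * xcol[0] + w2 * xcol[1];
          for (int h = 1; h < H - 1; ++h) {
            ycol[h] += w0 * xcol[h - 1] + w1 * xcol[h] + w2 * xcol[h + 1];
          }
          ycol[H - 1] += w0 * xcol[H - 2] + w1 * xcol[H - 1];
        }
      }
      if (relu) {
        for (int h = 0; h < H; ++h) {
          if (ycol[h] < 0) ycol[h] = 0;
        }
      }
    }
  }
  return y;
}

// Backward pass of cpp_conv3_fw. dy: [H,W,Cout].
// Returns list(dx = [H,W,Cin], dw = [3,3,Cin,Cout], db = [Cout]).
// [[Rcpp::export]]
List cpp_conv3_bw(NumericVector x, NumericVector w, NumericVector dy,
                  int H, int W, int Cin, int Cout) {
  NumericVector dx((R_xlen_t)H * W * Cin);
  NumericVector dw((R_xlen_t)9 * Cin * Cout);
  NumericVector db(Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int co = 0; co < Cout; ++co) {
    double bsum = 0.0;
    const double* dyc0 = dyp + (R_xlen_t)H * W * co;
    for (R_xlen_t i = 0; i < (R_xlen_t)H * W; ++i) bsum += dyc0[i];
    db[co] = bsum;
    for (int wc = 0; wc < W; ++wc) {
      const double* dycol = dyp + (R_xlen_t)H * (wc + (R_xlen_t)W * co);
      for (int ci = 0; ci < Cin; ++ci) {
        for (int kw = 0; kw < 3; ++kw) {
          const int ws = wc + kw - 1;
          if (ws < 0 || ws >= W) continue;
          const double* xcol = xp + (R_xlen_t)H * (ws + (R_xlen_t)W * ci);
          double* dxcol = dxp + (R_xlen_t)H * (ws + (R_xlen_t)W * ci);
          for (int kh = 0; kh < 3; ++kh) {
            const R_xlen_t widx = kh + 3 * (kw + 3 * (ci + (R_xlen_t)Cin * co));
            const double wv = wp[widx];
            const int h0 = std::max(0, 1 - kh), h1 = std::min(H, H + 1 - kh);
            double wsum = 0.0;
            const double* xs = xcol + kh - 1;
            double* dxs = dxcol + kh - 1;
            for (int h = h0; h < h1; ++h) {
              const double g = dycol[h];
              wsum += g * xs[h];
              dxs[h] += g * wv;
            }
            dwp[widx] += wsum;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 average pooling, stride 2. H and W must be even.
// [[Rcpp::export]]
NumericVector cpp_avgpool2_fw(NumericVector x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      const double* c0 = xp + (R_xlen_t)H * (2 * wo + (R_xlen_t)W * c);
      const double* c1 = c0 + H;
      double* yc = yp + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * c);
      for (int ho = 0; ho < Ho; ++ho)
        yc[ho] = 0.25 * (c0[2 * ho] + c0[2 * ho + 1] + c1[2 * ho] + c1[2 * ho + 1]);
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bw(NumericVector dy, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * C);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      const double* dyc = dyp + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * c);
      double* c0 = dxp + (R_xlen_t)H * (2 * wo + (R_xlen_t)W * c);
      double* c1 = c0 + H;
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = 0.25 * dyc[ho];
        c0[2 * ho] = g; c0[2 * ho + 1] = g; c1[2 * ho] = g; c1[2 * ho + 1] = g;
      }
    }
  return dx;
}

// Nearest-neighbour integer upsampling by factor f.
// [[Rcpp::export]]
NumericVector cpp_upsample_nearest(NumericVector x, int H, int W, int C, int f) {
  const int Ho = H * f, Wo = W * f;
  NumericVector y((R_xlen_t)Ho * Wo * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      const double* xc = xp + (R_xlen_t)H * (wo / f + (R_xlen_t)W * c);
      double* yc = yp + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * c);
      for (int ho = 0; ho < Ho; ++ho) yc[ho] = xc[ho / f];
    }
  return y;
}

// Gradient of nearest upsampling: sum over each f x f block.
// dy: [H*f, W*f, C] -> [H, W, C]
// [[Rcpp::export]]
NumericVector cpp_upsample_nearest_bw(NumericVector dy, int H, int W, int C, int f) {
  const int Hi = H * f, Wi = W * f;
  NumericVector dx((R_xlen_t)H * W * C);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int wi = 0; wi < Wi; ++wi) {
      const double* dyc = dyp + (R_xlen_t)Hi * (wi + (R_xlen_t)Wi * c);
      double* dxc = dxp + (R_xlen_t)H * (wi / f + (R_xlen_t)W * c);
      for (int hi = 0; hi < Hi; ++hi) dxc[hi / f] += dyc[hi];
    }
  return dx;
}

// Area-average ("box integral") resampling of a real-valued source window
// [sx0, sx1) x [sy0, sy1) (in source pixel units, fractional allowed) onto an
// outH x outW grid. Equivalent to OpenCV INTER_AREA for downscaling.
// src: [H, W] single channel. Per-axis pixel coverages are precomputed once.
static void coverage_spans(double s0, double s1, int n_out, int limit,
                           std::vector<int>& first, std::vector<int>& count,
                           std::vector<double>& weight) {
  const double b = (s1 - s0) / n_out;
  first.assign(n_out, 0);
  count.assign(n_out, 0);
  weight.clear();
  for (int o = 0; o < n_out; ++o) {
    double a0 = std::max(0.0, s0 + o * b);
    double a1 = std::min((double)limit, s0 + (o + 1) * b);
    first[o] = (int)std::floor(a0);
    for (int p = first[o]; p < a1; ++p) {
      const double cov = std::min((double)p + 1, a1) - std::max((double)p, a0);
      if (cov > 0) { weight.push_back(cov); ++count[o]; }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_area_resample(NumericMatrix src, double sy0, double sx0,
                                double sy1, double sx1, int outH, int outW) {
  const int H = src.nrow(), W = src.ncol();
  NumericMatrix out(outH, outW);
  std::vector<int> fy, cy, fx, cx;
  std::vector<double> wy, wx;
  coverage_spans(sy0, sy1, outH, H, fy, cy, wy);
  coverage_spans(sx0, sx1, outW, W, fx, cx, wx);
  std::vector<int> offy(outH, 0), offx(outW, 0);
  for (int o = 1; o < outH; ++o) offy[o] = offy[o - 1] + cy[o - 1];
  for (int o = 1; o < outW; ++o) offx[o] = offx[o - 1] + cx[o - 1];
  const double* sp = src.begin();
  double* op = out.begin();
  for (int ox = 0; ox < outW; ++ox) {
    const int nx = cx[ox];
    const double* wxp = wx.data() + offx[ox];
    for (int oy = 0; oy < outH; ++oy) {
      const int ny = cy[oy];
      const double* wyp = wy.data() + offy[oy];
      double acc = 0.0, wsum = 0.0;
      for (int j = 0; j < nx; ++j) {
        const double* col = sp + (size_t)H * (fx[ox] + j) + fy[oy];
        double cacc = 0.0, cw = 0.0;
        for (int i = 0; i < ny; ++i) {
          cacc += wyp[i] * col[i];
          cw += wyp[i];
        }
        acc += wxp[j] * cacc;
        wsum += wxp[j] * cw;
      }
      op[oy + (size_t)outH * ox] = wsum > 0 ? acc / wsum : 0.0;
    }
  }
  return out;
}

// Multi-channel variant operating directly on an [H, W, C] array without
// materialising per-channel copies.
// [[Rcpp::export]]
NumericVector cpp_area_resample_multi(NumericVector src, int H, int W, int C,
                                      double sy0, double sx0,
                                      double sy1, double sx1,
                                      int outH, int outW) {
  NumericVector out((R_xlen_t)outH * outW * C);
  std::vector<int> fy, cy, fx, cx;
  std::vector<double> wy, wx;
  coverage_spans(sy0, sy1, outH, H, fy, cy, wy);
  coverage_spans(sx0, sx1, outW, W, fx, cx, wx);
  std::vector<int> offy(outH, 0), offx(outW, 0);
  for (int o = 1; o < outH; ++o) offy[o] = offy[o - 1] + cy[o - 1];
  for (int o = 1; o < outW; ++o) offx[o] = offx[o - 1] + cx[o - 1];
  for (int c = 0; c < C; ++c) {
    const double* sp = src.begin() + (R_xlen_t)H * W * c;
    double* op = out.begin() + (R_xlen_t)outH * outW * c;
    for (int ox = 0; ox < outW; ++ox) {
      const int nx = cx[ox];
      const double* wxp = wx.data() + offx[ox];
      for (int oy = 0; oy < outH; ++oy) {
        const int ny = cy[oy];
        const double* wyp = wy.data() + offy[oy];
        double acc = 0.0, wsum = 0.0;
        for (int j = 0; j < nx; ++j) {
          const double* col = sp + (size_t)H * (fx[ox] + j) + fy[oy];
          double cacc = 0.0, cw = 0.0;
          for (int i = 0; i < ny; ++i) {
            cacc += wyp[i] * col[i];
            cw += wyp[i];
          }
          acc += wxp[j] * cacc;
          wsum += wxp[j] * cw;
        }
        op[oy + (size_t)outH * ox] = wsum > 0 ? acc / wsum : 0.0;
      }
    }
  }
  return out;
}

// Bilinear resize with half-pixel centre alignment (OpenCV INTER_LINEAR).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix src, int outH, int outW) {
  const int H = src.nrow(), W = src.ncol();
  NumericMatrix out(outH, outW);
  const double sy = (double)H / outH, sx = (double)W / outW;
  for (int ox = 0; ox < outW; ++ox) {
    double fx = (ox + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(fx);
    double ax = fx - x0;
    int x1 = x0 + 1;
    if (x0 < 0) { x0 = 0; x1 = 0; ax = 0; }
    if (x1 >= W) { x1 = W - 1; if (x0 >= W) x0 = W - 1; }
    for (int oy = 0; oy < outH; ++oy) {
      double fy = (oy + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(fy);
      double ay = fy - y0;
      int y1 = y0 + 1;
      if (y0 < 0) { y0 = 0; y1 = 0; ay = 0; }
      if (y1 >= H) { y1 = H - 1; if (y0 >= H) y0 = H - 1; }
      out(oy, ox) = (1 - ay) * ((1 - ax) * src(y0, x0) + ax * src(y0, x1)) +
                    ay * ((1 - ax) * src(y1, x0) + ax * src(y1, x1));
    }
  }
  return out;
}

// Connected-component labelling of a binary mask. Labels are assigned in
// raster-scan order (rows top to bottom, then columns left to right) of each
// component's first pixel, so the labelling is deterministic.
// conn: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int conn) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dy4[] = {-1, 1, 0, 0}, dx4[] = {0, 0, -1, 1};
  const int dy8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dx8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dy = conn == 8 ? dy8 : dy4;
  const int* dx = conn == 8 ? dx8 : dx4;
  const int nd = conn == 8 ? 8 : 4;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      stack.push_back(y + H * x);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int py = p % H, px = p / H;
        for (int d = 0; d < nd; ++d) {
          const int qy = py + dy[d], qx = px + dx[d];
          if (qy < 0 || qy >= H || qx < 0 || qx >= W) continue;
          if (mask(qy, qx) != 0 && lab(qy, qx) == 0) {
            lab(qy, qx) = next;
            stack.push_back(qy + H * qx);
          }
        }
      }
    }
  return lab;
}

// Median filter with a (2r+1) x (2r+1) square window and replicated borders.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int r) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const int n = (2 * r + 1) * (2 * r + 1);
  std::vector<double> win(n);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int k = 0;
      for (int dx = -r; dx <= r; ++dx) {
        int xs = std::min(W - 1, std::max(0, x + dx));
        const double* col = &img(0, xs);
        for (int dyy = -r; dyy <= r; ++dyy) {
          int ys = std::min(H - 1, std::max(0, y + dyy));
          win[k++] = col[ys];
        }
      }
      std::nth_element(win.begin(), win.begin() + n / 2, win.end());
      out(y, x) = win[n / 2];
    }
  return out;
}

// Disk stamping for the synthetic-slide renderer: paints filled disks
// (cy, cx, radius in pixel units, one colour per disk and channel) into an
// [H, W, C] canvas, modifying it in place.
// [[Rcpp::export]]
NumericVector cpp_stamp_disks(NumericVector canvas, int H, int W, int C,
                              NumericVector cy, NumericVector cx,
                              NumericVector radius, NumericMatrix colour) {
  double* cp = canvas.begin();
  const int n = cy.size();
  for (int i = 0; i < n; ++i) {
    const double r = radius[i], r2 = r * r;
    const int y0 = std::max(0, (int)std::ceil(cy[i] - r));
    const int y1 = std::min(H - 1, (int)std::floor(cy[i] + r));
    const int x0 = std::max(0, (int)std::ceil(cx[i] - r));
    const int x1 = std::min(W - 1, (int)std::floor(cx[i] + r));
    for (int x = x0; x <= x1; ++x) {
      const double ddx = x - cx[i];
      for (int y = y0; y <= y1; ++y) {
        const double ddy = y - cy[i];
        if (ddx * ddx + ddy * ddy <= r2)
          for (int c = 0; c < C; ++c)
            cp[y + (R_xlen_t)H * (x + (R_xlen_t)W * c)] = colour(i, c);
      }
    }
  }
  return canvas;
}
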