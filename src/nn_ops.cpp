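// Low-level numerical primitives: im2col convolution (valid or zero-padded),
// 2x2 max pooling, 2x2-stride-2 transposed convolution, bilinear resize,
// 8-connected component labeling and even-odd polygon rasterization.
// Tensors are R arrays in column-major order with dim (H, W, C, N).
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

static inline int dim_i(const NumericVector &x, int k) {
  IntegerVector d = x.attr("dim");
  return d[k];
}

// im2col for one sample: returns (Hout*Wout) x (k*k*Cin)
static void im2col_one(const double *x, int H, int W, int C, int k, int pad,
                       arma::mat &out) {
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * ci);
        double *dst = out.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + kw - pad;
          const bool wok = wi >= 0 && wi < W;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + kh - pad;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = x[hi + H * (wi + W * ci)];
            dst[ho + Ho * wo] = v;
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col_one
static void col2im_one(const arma::mat &cols, int H, int W, int C, int k,
                       int pad, double *x) {
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * ci);
        const double *src = cols.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + kw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + kh - pad;
            if (hi < 0 || hi >= H) continue;
            x[hi + H * (wi + W * ci)] += src[ho + Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int pad) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int k = dim_i(w, 0), Cout = dim_i(w, 3);
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  arma::mat Wm(const_cast<double *>(w.begin()), k * k * C, Cout, false, true);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (R_xlen_t)H * W * C * n, H, W, C, k, pad, cols);
    arma::mat out = cols * Wm; // (Ho*Wo) x Cout
    double *yp = y.begin() + (R_xlen_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double *oc = out.colptr(co);
      const double bb = b[co];
      double *yc = yp + (R_xlen_t)Ho * Wo * co;
      for (int i = 0; i < Ho * Wo; ++i) yc[i] = oc[i] + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int k = dim_i(w, 0), Cout = dim_i(w, 3);
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  arma::mat Wm(const_cast<double *>(w.begin()), k * k * C, Cout, false, true);
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  arma::mat GW(gw.begin(), k * k * C, Cout, false, true);
  arma::mat cols(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double *>(gy.begin()) + (R_xlen_t)Ho * Wo * Cout * n,
                 Ho * Wo, Cout, false, true);
    im2col_one(x.begin() + (R_xlen_t)H * W * C * n, H, W, C, k, pad, cols);
    GW += cols.t() * Gy;
    arma::mat Gcols = Gy * Wm.t();
    col2im_one(Gcols, H, W, C, k, pad,
               gx.begin() + (R_xlen_t)H * W * C * n);
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(Gy.col(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size()); // linear index into x of each max
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + (R_xlen_t)H * W * (c + C * n);
      double *yp = y.begin() + (R_xlen_t)Ho * Wo * (c + C * n);
      int *ip = idx.begin() + (R_xlen_t)Ho * Wo * (c + C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int best = 2 * ho + H * (2 * wo);
          double bv = xp[best];
          const int cand[3] = {2 * ho + 1 + H * (2 * wo),
                               2 * ho + H * (2 * wo + 1),
                               2 * ho + 1 + H * (2 * wo + 1)};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          yp[ho + Ho * wo] = bv;
          ip[ho + Ho * wo] = best + H * W * (c + C * n);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx,
                           IntegerVector xdim) {
  R_xlen_t sz = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(sz);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// transposed convolution, kernel 2x2, stride 2 (doubles spatial size)
// [[Rcpp::export]]
NumericVector upconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int Cout = dim_i(w, 3);
  NumericVector y((R_xlen_t)4 * H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout, N);
  const int Ho = 2 * H, Wo = 2 * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *yp = y.begin() + (R_xlen_t)Ho * Wo * (co + Cout * n);
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i) yp[i] = b[co];
      for (int ci = 0; ci < C; ++ci) {
        const double *xp = x.begin() + (R_xlen_t)H * W * (ci + C * n);
        const double w00 = w[0 + 2 * (0 + 2 * (ci + C * co))];
        const double w10 = w[1 + 2 * (0 + 2 * (ci + C * co))];
        const double w01 = w[0 + 2 * (1 + 2 * (ci + C * co))];
        const double w11 = w[1 + 2 * (1 + 2 * (ci + C * co))];
        for (int wi = 0; wi < W; ++wi)
          for (int hi = 0; hi < H; ++hi) {
            const double v = xp[hi + H * wi];
            double *o = yp + 2 * hi + Ho * (2 * wi);
            o[0] += v * w00;
            o[1] += v * w10;
            o[Ho] += v * w01;
            o[Ho + 1] += v * w11;
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List upconv2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int Cout = dim_i(w, 3);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *gp = gy.begin() + (R_xlen_t)Ho * Wo * (co + Cout * n);
      double s = 0;
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i) s += gp[i];
      gb[co] += s;
      for (int ci = 0; ci < C; ++ci) {
        const double *xp = x.begin() + (R_xlen_t)H * W * (ci + C * n);
        double *gxp = gx.begin() + (R_xlen_t)H * W * (ci + C * n);
        const double w00 = w[0 + 2 * (0 + 2 * (ci + C * co))];
        const double w10 = w[1 + 2 * (0 + 2 * (ci + C * co))];
        const double w01 = w[0 + 2 * (1 + 2 * (ci + C * co))];
        const double w11 = w[1 + 2 * (1 + 2 * (ci + C * co))];
        double a00 = 0, a10 = 0, a01 = 0, a11 = 0;
        for (int wi = 0; wi < W; ++wi)
          for (int hi = 0; hi < H; ++hi) {
            const double *o = gp + 2 * hi + Ho * (2 * wi);
            const double v = xp[hi + H * wi];
            gxp[hi + H * wi] +=
                o[0] * w00 + o[1] * w10 + o[Ho] * w01 + o[Ho + 1] * w11;
            a00 += v * o[0];
            a10 += v * o[1];
            a01 += v * o[Ho];
            a11 += v * o[Ho + 1];
          }
        gw[0 + 2 * (0 + 2 * (ci + C * co))] += a00;
        gw[1 + 2 * (0 + 2 * (ci + C * co))] += a10;
        gw[0 + 2 * (1 + 2 * (ci + C * co))] += a01;
        gw[1 + 2 * (1 + 2 * (ci + C * co))] += a11;
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericMatrix bilinear_resize(NumericMatrix x, int out_h, int out_w) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(out_h, out_w);
  const double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    double sc = (j + 0.5) * sw - 0.5;
    if (sc < 0) sc = 0;
    if (sc > W - 1) sc = W - 1;
    const int c0 = (int)sc, c1 = c0 + 1 < W ? c0 + 1 : c0;
    const double fc = sc - c0;
    for (int i = 0; i < out_h; ++i) {
      double sr = (i + 0.5) * sh - 0.5;
      if (sr < 0) sr = 0;
      if (sr > H - 1) sr = H - 1;
      const int r0 = (int)sr, r1 = r0 + 1 < H ? r0 + 1 : r0;
      const double fr = sr - r0;
      y(i, j) = (1 - fr) * ((1 - fc) * x(r0, c0) + fc * x(r0, c1)) +
                fr * ((1 - fc) * x(r1, c0) + fc * x(r1, c1));
    }
  }
  return y;
}

// 8-connected component labeling of a binary matrix (0/1), BFS.
// [[Rcpp::export]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(r + H * c);
      while (!q.empty()) {
        const int p = q.front();
        q.pop();
        const int pr = p % H, pc = p / H;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            const int nr = pr + dr, nc = pc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              q.push(nr + H * nc);
            }
          }
      }
    }
  return lab;
}

// Even-odd scanline rasterization of a closed polygon given as (row, col)
// vertex coordinates in pixel-center units (1-based).
// [[Rcpp::export]]
IntegerMatrix polygon_fill(NumericMatrix verts, int H, int W) {
  IntegerMatrix out(H, W);
  const int n = verts.nrow();
  std::vector<double> xs;
  for (int r = 1; r <= H; ++r) {
    xs.clear();
    const double y = (double)r;
    for (int i = 0; i < n; ++i) {
      const int j = (i + 1) % n;
      const double y1 = verts(i, 0), y2 = verts(j, 0);
      const double x1 = verts(i, 1), x2 = verts(j, 1);
      if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
        const double t = (y - y1) / (y2 - y1);
        xs.push_back(x1 + t * (x2 - x1));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k] - 1e-9);
      int c1 = (int)std::floor(xs[k + 1] + 1e-9);
      if (c0 < 1) c0 = 1;
      if (c1 > W) c1 = W;
      for (int c = c0; c <= c1; ++c) out(r - 1, c - 1) = 1;
    }
  }
  return out;
}
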