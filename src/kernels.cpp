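// Numerical kernels: 2-D convolution (forward/backward, im2col + GEMM),
// backward bilinear warping (forward/backward), bilinear resizing,
// capsule/segment rasterization for the simulator, and Zhang-Suen thinning.
//
// Array layout convention (matches R): column-major with dim (H, W, C),
// i.e. element (i, j, c) sits at i + H*j + H*W*c.  Flow fields are
// (H, W, 2) with channel 1 = dx (column offset) and channel 2 = dy (row
// offset), both in pixels.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// im2col: (H, W, Cin) -> (Ho*Wo, kh*kw*Cin) with zero padding `pad`
// (applied on both axes), stride `s`.  Kernels may be rectangular
// (kh x kw), which lets separable filters run cheaply.
// ---------------------------------------------------------------------------
static void im2col_fill(arma::mat& M, const double* x, int H, int W, int Cin,
                        int kh, int kw, int pad, int s, int Ho, int Wo) {
  M.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int col = ki + kh * kj + kh * kw * c;
        double* Mcol = M.colptr(col);
        // valid output ranges (bounds hoisted out of the loops)
        int io_lo = std::max(0, (pad - ki + s - 1) / s);
        int io_hi = std::min(Ho - 1, (H - 1 + pad - ki) / s);
        int jo_lo = std::max(0, (pad - kj + s - 1) / s);
        int jo_hi = std::min(Wo - 1, (W - 1 + pad - kj) / s);
        if (io_hi < io_lo || jo_hi < jo_lo) continue;
        for (int jo = jo_lo; jo <= jo_hi; ++jo) {
          int jin = jo * s - pad + kj;
          const double* src = xc + (size_t)H * jin + (io_lo * s - pad + ki);
          double* dst = Mcol + io_lo + (size_t)Ho * jo;
          int n = io_hi - io_lo + 1;
          if (s == 1) {
            std::memcpy(dst, src, n * sizeof(double));
          } else {
            for (int t = 0; t < n; ++t) dst[t] = src[(size_t)t * s];
          }
        }
      }
    }
  }
}

static void col2im_add(double* gx, const arma::mat& gM, int H, int W, int Cin,
                       int kh, int kw, int pad, int s, int Ho, int Wo) {
  for (int c = 0; c < Cin; ++c) {
    double* gxc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int col = ki + kh * kj + kh * kw * c;
        const double* gMcol = gM.colptr(col);
        int io_lo = std::max(0, (pad - ki + s - 1) / s);
        int io_hi = std::min(Ho - 1, (H - 1 + pad - ki) / s);
        int jo_lo = std::max(0, (pad - kj + s - 1) / s);
        int jo_hi = std::min(Wo - 1, (W - 1 + pad - kj) / s);
        if (io_hi < io_lo || jo_hi < jo_lo) continue;
        for (int jo = jo_lo; jo <= jo_hi; ++jo) {
          int jin = jo * s - pad + kj;
          double* dst = gxc + (size_t)H * jin + (io_lo * s - pad + ki);
          const double* src = gMcol + io_lo + (size_t)Ho * jo;
          int n = io_hi - io_lo + 1;
          if (s == 1) {
            for (int t = 0; t < n; ++t) dst[t] += src[t];
          } else {
            for (int t = 0; t < n; ++t) dst[(size_t)t * s] += src[t];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;

  arma::mat M(Ho * Wo, kh * kw * Cin);
  im2col_fill(M, x.begin(), H, W, Cin, kh, kw, pad, stride, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat Y = M * Wm;
  for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];

  NumericVector out(Ho * Wo * Cout);
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// forward that also returns the im2col workspace for reuse in backward
// [[Rcpp::export]]
List cpp_conv2d_forward_ws(NumericVector x, NumericVector w,
                           NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;

  NumericMatrix Mr(Ho * Wo, kh * kw * Cin);
  arma::mat M(Mr.begin(), Ho * Wo, kh * kw * Cin, false, true);
  im2col_fill(M, x.begin(), H, W, Cin, kh, kw, pad, stride, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat Y = M * Wm;
  for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];

  NumericVector out(Ho * Wo * Cout);
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return List::create(_["y"] = out, _["M"] = Mr);
}

// backward reusing the cached im2col matrix; gradient computations can be
// skipped for constant inputs (want_gx) or frozen kernels (want_gw)
// [[Rcpp::export]]
List cpp_conv2d_backward_ws(NumericMatrix Mr, IntegerVector xd,
                            NumericVector w, NumericVector gy,
                            int stride, int pad,
                            bool want_gx, bool want_gw) {
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];

  arma::mat M(Mr.begin(), Mr.nrow(), Mr.ncol(), false, true);
  arma::mat G(const_cast<double*>(gy.begin()), Ho * Wo, Cout, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);

  List out = List::create(_["gx"] = R_NilValue, _["gw"] = R_NilValue,
                          _["gb"] = R_NilValue);
  if (want_gw) {
    arma::mat gW = M.t() * G;
    arma::rowvec gB = arma::sum(G, 0);
    NumericVector gw(kh * kw * Cin * Cout);
    std::copy(gW.begin(), gW.end(), gw.begin());
    gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
    NumericVector gb(Cout);
    std::copy(gB.begin(), gB.end(), gb.begin());
    out["gw"] = gw;
    out["gb"] = gb;
  }
  if (want_gx) {
    arma::mat gM = G * Wm.t();
    NumericVector gx(H * W * Cin);
    col2im_add(gx.begin(), gM, H, W, Cin, kh, kw, pad, stride, Ho, Wo);
    gx.attr("dim") = IntegerVector::create(H, W, Cin);
    out["gx"] = gx;
  }
  return out;
}

// standalone backward (recomputes im2col); kept for oracle tests
// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];

  arma::mat M(Ho * Wo, kh * kw * Cin);
  im2col_fill(M, x.begin(), H, W, Cin, kh, kw, pad, stride, Ho, Wo);
  arma::mat G(const_cast<double*>(gy.begin()), Ho * Wo, Cout, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);

  arma::mat gW = M.t() * G;
  arma::rowvec gB = arma::sum(G, 0);
  arma::mat gM = G * Wm.t();

  NumericVector gx(H * W * Cin);
  col2im_add(gx.begin(), gM, H, W, Cin, kh, kw, pad, stride, Ho, Wo);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);

  NumericVector gw(kh * kw * Cin * Cout);
  std::copy(gW.begin(), gW.end(), gw.begin());
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector gb(Cout);
  std::copy(gB.begin(), gB.end(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Backward bilinear warp: out(r, c) = x(r + dy(r,c), c + dx(r,c)), border clamp
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_warp_forward(NumericVector x, NumericVector flow) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd.size() > 2 ? xd[2] : 1;
  const double* dx = flow.begin();
  const double* dy = flow.begin() + (size_t)H * W;

  NumericVector out(H * W * C);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double sr = clampd(i + dy[i + H * j], 0.0, H - 1.0);
      double sc = clampd(j + dx[i + H * j], 0.0, W - 1.0);
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      double fr = sr - r0, fc = sc - c0;
      for (int ch = 0; ch < C; ++ch) {
        const double* xc = x.begin() + (size_t)H * W * ch;
        double v00 = xc[r0 + H * c0], v10 = xc[r1 + H * c0];
        double v01 = xc[r0 + H * c1], v11 = xc[r1 + H * c1];
        out[i + H * j + (size_t)H * W * ch] =
          (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
          (1 - fr) * fc * v01 + fr * fc * v11;
      }
    }
  }
  out.attr("dim") = xd;
  return out;
}

// [[Rcpp::export]]
List cpp_warp_backward(NumericVector x, NumericVector flow, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd.size() > 2 ? xd[2] : 1;
  const double* dx = flow.begin();
  const double* dy = flow.begin() + (size_t)H * W;

  NumericVector gx(H * W * C);
  NumericVector gflow(H * W * 2);
  double* gdx = gflow.begin();
  double* gdy = gflow.begin() + (size_t)H * W;

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double sr_raw = i + dy[i + H * j];
      double sc_raw = j + dx[i + H * j];
      bool in_r = sr_raw > 0.0 && sr_raw < H - 1.0;  // clamp kills flow grad
      bool in_c = sc_raw > 0.0 && sc_raw < W - 1.0;
      double sr = clampd(sr_raw, 0.0, H - 1.0);
      double sc = clampd(sc_raw, 0.0, W - 1.0);
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      double fr = sr - r0, fc = sc - c0;
      double gr = 0.0, gc = 0.0;
      for (int ch = 0; ch < C; ++ch) {
        const double* xc = x.begin() + (size_t)H * W * ch;
        double* gxc = gx.begin() + (size_t)H * W * ch;
        double g = gy[i + H * j + (size_t)H * W * ch];
        double v00 = xc[r0 + H * c0], v10 = xc[r1 + H * c0];
        double v01 = xc[r0 + H * c1], v11 = xc[r1 + H * c1];
        gxc[r0 + H * c0] += g * (1 - fr) * (1 - fc);
        gxc[r1 + H * c0] += g * fr * (1 - fc);
        gxc[r0 + H * c1] += g * (1 - fr) * fc;
        gxc[r1 + H * c1] += g * fr * fc;
        gr += g * ((1 - fc) * (v10 - v00) + fc * (v11 - v01));
        gc += g * ((1 - fr) * (v01 - v00) + fr * (v11 - v10));
      }
      if (in_r) gdy[i + H * j] = gr;
      if (in_c) gdx[i + H * j] = gc;
    }
  }
  gx.attr("dim") = xd;
  gflow.attr("dim") = IntegerVector::create(H, W, 2);
  return List::create(_["gx"] = gx, _["gflow"] = gflow);
}

// ---------------------------------------------------------------------------
// Bilinear resize with half-pixel centers (continuous-tone resampling)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int out_h, int out_w) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(out_h, out_w);
  double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    double scc = clampd((j + 0.5) * sx - 0.5, 0.0, W - 1.0);
    int c0 = (int)std::floor(scc);
    int c1 = std::min(c0 + 1, W - 1);
    double fc = scc - c0;
    for (int i = 0; i < out_h; ++i) {
      double srr = clampd((i + 0.5) * sy - 0.5, 0.0, H - 1.0);
      int r0 = (int)std::floor(srr);
      int r1 = std::min(r0 + 1, H - 1);
      double fr = srr - r0;
      out(i, j) = (1 - fr) * (1 - fc) * x(r0, c0) + fr * (1 - fc) * x(r1, c0) +
                  (1 - fr) * fc * x(r0, c1) + fr * fc * x(r1, c1);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rasterize thick 2-D segments as additive optical density.
// segs: n x 5 matrix (x0, y0, x1, y1, half_width) in pixel coordinates
// (x = column, y = row, 0-based); density: per-segment darkness scale.
// Edge profile: linear anti-aliasing ramp of one pixel.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_draw_segments(int H, int W, NumericMatrix segs,
                                NumericVector density) {
  NumericMatrix out(H, W);
  int n = segs.nrow();
  for (int s = 0; s < n; ++s) {
    double x0 = segs(s, 0), y0 = segs(s, 1), x1 = segs(s, 2), y1 = segs(s, 3);
    double hw = segs(s, 4), den = density[s];
    if (den <= 0.0) continue;
    int jlo = std::max(0, (int)std::floor(std::min(x0, x1) - hw - 1));
    int jhi = std::min(W - 1, (int)std::ceil(std::max(x0, x1) + hw + 1));
    int ilo = std::max(0, (int)std::floor(std::min(y0, y1) - hw - 1));
    int ihi = std::min(H - 1, (int)std::ceil(std::max(y0, y1) + hw + 1));
    double vx = x1 - x0, vy = y1 - y0;
    double len2 = vx * vx + vy * vy;
    for (int j = jlo; j <= jhi; ++j) {
      for (int i = ilo; i <= ihi; ++i) {
        double px = j - x0, py = i - y0;
        double t = len2 > 0 ? clampd((px * vx + py * vy) / len2, 0.0, 1.0) : 0.0;
        double ddx = px - t * vx, ddy = py - t * vy;
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        double cov = clampd(hw + 0.5 - d, 0.0, 1.0);  // 1 inside, ramp at edge
        if (cov > 0) out(i, j) += den * cov;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_draw_disc(NumericMatrix canvas, double cx, double cy,
                            double radius, double density) {
  int H = canvas.nrow(), W = canvas.ncol();
  NumericMatrix out = clone(canvas);
  int jlo = std::max(0, (int)std::floor(cx - radius - 1));
  int jhi = std::min(W - 1, (int)std::ceil(cx + radius + 1));
  int ilo = std::max(0, (int)std::floor(cy - radius - 1));
  int ihi = std::min(H - 1, (int)std::ceil(cy + radius + 1));
  for (int j = jlo; j <= jhi; ++j)
    for (int i = ilo; i <= ihi; ++i) {
      double d = std::sqrt((j - cx) * (j - cx) + (i - cy) * (i - cy));
      double cov = clampd(radius + 0.5 - d, 0.0, 1.0);
      if (cov > 0) out(i, j) += density * cov;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Zhang-Suen thinning of a binary image (1 = foreground)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix img) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix a = clone(img);
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 1; j < W - 1; ++j) {
        for (int i = 1; i < H - 1; ++i) {
          if (!a(i, j)) continue;
          int p2 = a(i - 1, j), p3 = a(i - 1, j + 1), p4 = a(i, j + 1),
              p5 = a(i + 1, j + 1), p6 = a(i + 1, j), p7 = a(i + 1, j - 1),
              p8 = a(i, j - 1), p9 = a(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      for (size_t t = 0; t < kill.size(); ++t) a(kill[t].first, kill[t].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return a;
}
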