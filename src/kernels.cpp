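// Compiled numeric kernels. Feature maps are stored as N x C matrices with
// tokens in row-major spatial order: token t = r*W + c (0-based). Coordinates
// are (row, col), 0-based; sampling outside [0,H-1]x[0,W-1] reads zeros.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------- im2col ----

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& X, int H, int W,
                         int kh, int kw, int stride, int pad) {
  const int C = X.ncol();
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(Ho * Wo, kh * kw * C);
  for (int ro = 0; ro < Ho; ++ro) {
    for (int co = 0; co < Wo; ++co) {
      const int to = ro * Wo + co;
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ro * stride - pad + ki;
        for (int kj = 0; kj < kw; ++kj) {
          const int c = co * stride - pad + kj;
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          const int t = r * W + c;
          const int base = (ki * kw + kj) * C;
          for (int ch = 0; ch < C; ++ch) out(to, base + ch) = X(t, ch);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& dCol, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix dX(H * W, C);
  for (int ro = 0; ro < Ho; ++ro) {
    for (int co = 0; co < Wo; ++co) {
      const int to = ro * Wo + co;
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ro * stride - pad + ki;
        for (int kj = 0; kj < kw; ++kj) {
          const int c = co * stride - pad + kj;
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          const int t = r * W + c;
          const int base = (ki * kw + kj) * C;
          for (int ch = 0; ch < C; ++ch) dX(t, ch) += dCol(to, base + ch);
        }
      }
    }
  }
  return dX;
}

// ------------------------------------------------------- depthwise conv ----

// Wd: (kh*kw) x C, stride 1.
// [[Rcpp::export]]
NumericMatrix dwconv_fwd_cpp(const NumericMatrix& X, int H, int W,
                             const NumericMatrix& Wd, const NumericVector& b,
                             int kh, int kw, int pad) {
  const int C = X.ncol();
  NumericMatrix Y(H * W, C);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      const int t = r * W + c;
      for (int ch = 0; ch < C; ++ch) Y(t, ch) = b[ch];
      for (int ki = 0; ki < kh; ++ki) {
        const int rr = r - pad + ki;
        if (rr < 0 || rr >= H) continue;
        for (int kj = 0; kj < kw; ++kj) {
          const int cc = c - pad + kj;
          if (cc < 0 || cc >= W) continue;
          const int ts = rr * W + cc, k = ki * kw + kj;
          for (int ch = 0; ch < C; ++ch) Y(t, ch) += Wd(k, ch) * X(ts, ch);
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& X,
                    int H, int W, const NumericMatrix& Wd,
                    int kh, int kw, int pad) {
  const int C = X.ncol();
  NumericMatrix dX(H * W, C), dW(kh * kw, C);
  NumericVector db(C);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      const int t = r * W + c;
      for (int ch = 0; ch < C; ++ch) db[ch] += dY(t, ch);
      for (int ki = 0; ki < kh; ++ki) {
        const int rr = r - pad + ki;
        if (rr < 0 || rr >= H) continue;
        for (int kj = 0; kj < kw; ++kj) {
          const int cc = c - pad + kj;
          if (cc < 0 || cc >= W) continue;
          const int ts = rr * W + cc, k = ki * kw + kj;
          for (int ch = 0; ch < C; ++ch) {
            dW(k, ch) += dY(t, ch) * X(ts, ch);
            dX(ts, ch) += dY(t, ch) * Wd(k, ch);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dX, _["dw"] = dW, _["db"] = db);
}

// ---------------------------------------------- deformable aggregation ----

// Bilinear read with zero padding; also returns corner data for gradients.
static inline double bil_read(const NumericMatrix& X, int H, int W, int ch,
                              double r, double c) {
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  const double fr = r - r0, fc = c - c0;
  double v = 0.0;
  for (int dr = 0; dr < 2; ++dr) {
    const int rr = r0 + dr;
    if (rr < 0 || rr >= H) continue;
    const double wr = dr ? fr : 1.0 - fr;
    if (wr == 0.0) continue;
    for (int dc = 0; dc < 2; ++dc) {
      const int cc = c0 + dc;
      if (cc < 0 || cc >= W) continue;
      const double w = wr * (dc ? fc : 1.0 - fc);
      if (w != 0.0) v += w * X(rr * W + cc, ch);
    }
  }
  return v;
}

// X: N x C; offs: N x (2*G*K), column (g*K+k)*2 + d with d=0 -> drow, d=1 -> dcol;
// mods: N x (G*K); grid: K x 2 integer (drow, dcol).
// [[Rcpp::export]]
NumericMatrix deform_agg_fwd_cpp(const NumericMatrix& X, int H, int W, int G,
                                 const NumericMatrix& offs,
                                 const NumericMatrix& mods,
                                 const IntegerMatrix& grid) {
  const int C = X.ncol(), K = grid.nrow(), Cp = C / G;
  NumericMatrix S(H * W, C);
  for (int t = 0; t < H * W; ++t) {
    const int r = t / W, c = t % W;
    for (int g = 0; g < G; ++g) {
      for (int k = 0; k < K; ++k) {
        const double m = mods(t, g * K + k);
        if (m == 0.0) continue;
        const double sr = r + grid(k, 0) + offs(t, (g * K + k) * 2);
        const double sc = c + grid(k, 1) + offs(t, (g * K + k) * 2 + 1);
        for (int ch = 0; ch < Cp; ++ch)
          S(t, g * Cp + ch) += m * bil_read(X, H, W, g * Cp + ch, sr, sc);
      }
    }
  }
  return S;
}

// [[Rcpp::export]]
List deform_agg_bwd_cpp(const NumericMatrix& dS, const NumericMatrix& X,
                        int H, int W, int G,
                        const NumericMatrix& offs, const NumericMatrix& mods,
                        const IntegerMatrix& grid) {
  const int C = X.ncol(), K = grid.nrow(), Cp = C / G, N = H * W;
  NumericMatrix dX(N, C), dOffs(N, 2 * G * K), dMods(N, G * K);
  for (int t = 0; t < N; ++t) {
    const int r = t / W, c = t % W;
    for (int g = 0; g < G; ++g) {
      for (int k = 0; k < K; ++k) {
        const double m = mods(t, g * K + k);
        const double sr = r + grid(k, 0) + offs(t, (g * K + k) * 2);
        const double sc = c + grid(k, 1) + offs(t, (g * K + k) * 2 + 1);
        const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        const double fr = sr - r0, fc = sc - c0;
        double dmod = 0.0, drow = 0.0, dcol = 0.0;
        for (int ch = 0; ch < Cp; ++ch) {
          const int cg = g * Cp + ch;
          const double go = dS(t, cg);
          // corner values (zero outside)
          double v[2][2];
          for (int dr = 0; dr < 2; ++dr)
            for (int dc = 0; dc < 2; ++dc) {
              const int rr = r0 + dr, cc = c0 + dc;
              v[dr][dc] = (rr >= 0 && rr < H && cc >= 0 && cc < W)
                            ? X(rr * W + cc, cg) : 0.0;
            }
          const double val = (1 - fr) * ((1 - fc) * v[0][0] + fc * v[0][1]) +
                             fr * ((1 - fc) * v[1][0] + fc * v[1][1]);
          dmod += val * go;
          if (m != 0.0 || go != 0.0) {
            drow += go * ((1 - fc) * (v[1][0] - v[0][0]) +
                          fc * (v[1][1] - v[0][1]));
            dcol += go * ((1 - fr) * (v[0][1] - v[0][0]) +
                          fr * (v[1][1] - v[1][0]));
            // scatter into dX
            const double gm = go * m;
            if (gm != 0.0) {
              for (int dr = 0; dr < 2; ++dr) {
                const int rr = r0 + dr;
                if (rr < 0 || rr >= H) continue;
                const double wr = dr ? fr : 1.0 - fr;
                for (int dc = 0; dc < 2; ++dc) {
                  const int cc = c0 + dc;
                  if (cc < 0 || cc >= W) continue;
                  const double w = wr * (dc ? fc : 1.0 - fc);
                  if (w != 0.0) dX(rr * W + cc, cg) += gm * w;
                }
              }
            }
          }
        }
        dMods(t, g * K + k) += dmod;
        dOffs(t, (g * K + k) * 2) += m * drow;
        dOffs(t, (g * K + k) * 2 + 1) += m * dcol;
      }
    }
  }
  return List::create(_["dx"] = dX, _["doffs"] = dOffs, _["dmods"] = dMods);
}

// ------------------------------------------------------- bilinear resize ----

// align_corners = FALSE convention with border clamping.
static inline void src_coord(int i, int n_out, int n_in, int* i0, int* i1,
                             double* f) {
  double s = (i + 0.5) * (double)n_in / n_out - 0.5;
  if (s < 0) s = 0;
  if (s > n_in - 1) s = n_in - 1;
  *i0 = (int)std::floor(s);
  *i1 = *i0 + 1 < n_in ? *i0 + 1 : n_in - 1;
  *f = s - *i0;
}

// [[Rcpp::export]]
NumericMatrix bilinear_resize_fwd_cpp(const NumericMatrix& X, int H, int W,
                                      int Ho, int Wo) {
  const int C = X.ncol();
  NumericMatrix Y(Ho * Wo, C);
  for (int ro = 0; ro < Ho; ++ro) {
    int r0, r1; double fr;
    src_coord(ro, Ho, H, &r0, &r1, &fr);
    for (int co = 0; co < Wo; ++co) {
      int c0, c1; double fc;
      src_coord(co, Wo, W, &c0, &c1, &fc);
      const int to = ro * Wo + co;
      for (int ch = 0; ch < C; ++ch) {
        Y(to, ch) = (1 - fr) * ((1 - fc) * X(r0 * W + c0, ch) +
                                fc * X(r0 * W + c1, ch)) +
                    fr * ((1 - fc) * X(r1 * W + c0, ch) +
                          fc * X(r1 * W + c1, ch));
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix bilinear_resize_bwd_cpp(const NumericMatrix& dY, int H, int W,
                                      int Ho, int Wo, int C) {
  NumericMatrix dX(H * W, C);
  for (int ro = 0; ro < Ho; ++ro) {
    int r0, r1; double fr;
    src_coord(ro, Ho, H, &r0, &r1, &fr);
    for (int co = 0; co < Wo; ++co) {
      int c0, c1; double fc;
      src_coord(co, Wo, W, &c0, &c1, &fc);
      const int to = ro * Wo + co;
      for (int ch = 0; ch < C; ++ch) {
        const double g = dY(to, ch);
        if (g == 0.0) continue;
        dX(r0 * W + c0, ch) += (1 - fr) * (1 - fc) * g;
        dX(r0 * W + c1, ch) += (1 - fr) * fc * g;
        dX(r1 * W + c0, ch) += fr * (1 - fc) * g;
        dX(r1 * W + c1, ch) += fr * fc * g;
      }
    }
  }
  return dX;
}

// ------------------------------------------------- connected components ----

// 8-connectivity labelling of a binary mask (H x W matrix, 0/1).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r * W + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int t = stack.back();
        stack.pop_back();
        const int tr = t / W, tc = t % W;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            const int rr = tr + dr, cc = tc + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr * W + cc);
            }
          }
        }
      }
    }
  }
  return lab;
}
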