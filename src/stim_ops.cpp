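// Rasterization kernels for the stimulus generator: anti-aliased oriented
// bars (texture elements) and thick polylines (digit strokes), both
// composited with per-pixel max.

#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

// [[Rcpp::export]]
NumericMatrix cpp_draw_bars(NumericMatrix img_in, NumericVector cy,
                            NumericVector cx, const double theta_deg,
                            const double len, const double wid,
                            const double contrast) {
  NumericMatrix img = clone(img_in);
  const int H = img.nrow(), W = img.ncol();
  const double th = theta_deg * M_PI / 180.0;
  const double ux = std::cos(th), uy = -std::sin(th);
  const double half = len / 2.0 + wid / 2.0 + 1.0;
  for (int i = 0; i < cy.size(); ++i) {
    const int r0 = std::max(1, (int)std::floor(cy[i] - half));
    const int r1 = std::min(H, (int)std::ceil(cy[i] + half));
    const int c0 = std::max(1, (int)std::floor(cx[i] - half));
    const int c1 = std::min(W, (int)std::ceil(cx[i] + half));
    for (int c = c0; c <= c1; ++c) {
      const double dx = c - cx[i];
      for (int r = r0; r <= r1; ++r) {
        const double dy = r - cy[i];
        const double u = dx * ux + dy * uy;
        const double v = -dx * uy + dy * ux;
        const double cov = clamp01(wid / 2.0 + 0.5 - std::fabs(v)) *
          clamp01(len / 2.0 + 0.5 - std::fabs(u));
        const double val = contrast * cov;
        if (val > img(r - 1, c - 1)) img(r - 1, c - 1) = val;
      }
    }
  }
  return img;
}

// [[Rcpp::export]]
NumericMatrix cpp_draw_polyline(NumericMatrix img_in, NumericVector px,
                                NumericVector py, const double thick) {
  NumericMatrix img = clone(img_in);
  const int H = img.nrow(), W = img.ncol();
  for (int s = 0; s + 1 < px.size(); ++s) {
    const double x0 = px[s], y0 = py[s], x1 = px[s + 1], y1 = py[s + 1];
    const double L2 = (x1 - x0) * (x1 - x0) + (y1 - y0) * (y1 - y0);
    const int r0 = std::max(1, (int)std::floor(std::min(y0, y1) - thick));
    const int r1 = std::min(H, (int)std::ceil(std::max(y0, y1) + thick));
    const int c0 = std::max(1, (int)std::floor(std::min(x0, x1) - thick));
    const int c1 = std::min(W, (int)std::ceil(std::max(x0, x1) + thick));
    for (int c = c0; c <= c1; ++c) {
      for (int r = r0; r <= r1; ++r) {
        double t = 0.0;
        if (L2 > 1e-18)
          t = clamp01(((c - x0) * (x1 - x0) + (r - y0) * (y1 - y0)) / L2);
        const double qx = x0 + t * (x1 - x0), qy = y0 + t * (y1 - y0);
        const double d = std::sqrt((c - qx) * (c - qx) + (r - qy) * (r - qy));
        const double val = clamp01(thick / 2.0 + 0.5 - d);
        if (val > img(r - 1, c - 1)) img(r - 1, c - 1) = val;
      }
    }
  }
  return img;
}
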