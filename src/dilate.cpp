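#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest vertical distance (grayscale dilation by the reflected tip shape)
// over a set of lateral scan positions. The search is restricted to sample
// cells within rhoB of the tip axis; the result is floored at 0 (substrate
// contact). Grids are uniform; index windows keep the loop tight.
// [[Rcpp::export]]
NumericVector cvd_scan(NumericVector sx, NumericVector sy, NumericMatrix h,
                       double R, double theta, NumericMatrix pos, double rhoB) {
  const double rho_t = R * std::cos(theta);
  const double z_t = R * (1.0 - std::sin(theta));
  const double tanth = std::tan(theta);
  const int nx = sx.size(), ny = sy.size(), m = pos.nrow();
  const double dx = nx > 1 ? sx[1] - sx[0] : 1.0;
  const double dy = ny > 1 ? sy[1] - sy[0] : 1.0;
  const double rhoB2 = rhoB * rhoB;
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    const double px = pos(k, 0), py = pos(k, 1);
    int i0 = nx > 1 ? (int)std::ceil((px - rhoB - sx[0]) / dx) : 0;
    int i1 = nx > 1 ? (int)std::floor((px + rhoB - sx[0]) / dx) : 0;
    int j0 = ny > 1 ? (int)std::ceil((py - rhoB - sy[0]) / dy) : 0;
    int j1 = ny > 1 ? (int)std::floor((py + rhoB - sy[0]) / dy) : 0;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (i1 >= nx) i1 = nx - 1;
    if (j1 >= ny) j1 = ny - 1;
    double best = 0.0;
    for (int j = j0; j <= j1; ++j) {
      const double ddy = sy[j] - py;
      const double ddy2 = ddy * ddy;
      for (int i = i0; i <= i1; ++i) {
        const double ddx = sx[i] - px;
        const double d2 = ddx * ddx + ddy2;
        if (d2 > rhoB2) continue;
        const double rho = std::sqrt(d2);
        double tp;
        if (rho <= rho_t) {
          double s = R * R - rho * rho;
          tp = R - std::sqrt(s > 0.0 ? s : 0.0);
        } else {
          tp = z_t + (rho - rho_t) / tanth;
        }
        const double v = h(i, j) - tp;
        if (v > best) best = v;
      }
    }
    out[k] = best;
  }
  return out;
}
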