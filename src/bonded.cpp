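#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Harmonic pair bonds U = k_b (r - r0)^2. Returns per-particle force
// accumulators and the current length of every bond (for breakage checks).
// [[Rcpp::export]]
List cpp_bond_forces(IntegerVector bi, IntegerVector bj, NumericVector kb,
                     NumericVector r0, NumericVector x, NumericVector y,
                     int n) {
  const int nb = bi.size();
  NumericVector fx(n), fy(n), len(nb);
  for (int k = 0; k < nb; ++k) {
    int i = bi[k] - 1, j = bj[k] - 1;
    double dx = x[i] - x[j], dy = y[i] - y[j];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r <= 0.0)
      stop("coincident bonded particles (%d, %d): bond direction undefined",
           i + 1, j + 1);
    len[k] = r;
    double f = -2.0 * kb[k] * (r - r0[k]) / r; // restoring, along the bond
    fx[i] += f * dx; fy[i] += f * dy;
    fx[j] -= f * dx; fy[j] -= f * dy;
  }
  return List::create(_["fx"] = fx, _["fy"] = fy, _["length"] = len);
}

// Harmonic angle bonds U = k_a (theta - theta0)^2 with the vertex at j.
// theta is the interior angle between arms j->i and j->k, in [0, pi].
// [[Rcpp::export]]
List cpp_angle_forces(IntegerVector ai, IntegerVector aj, IntegerVector ak,
                      NumericVector ka, NumericVector th0,
                      NumericVector x, NumericVector y, int n) {
  const int na = ai.size();
  NumericVector fx(n), fy(n), theta(na);
  for (int m = 0; m < na; ++m) {
    int i = ai[m] - 1, j = aj[m] - 1, k = ak[m] - 1;
    double ux = x[i] - x[j], uyv = y[i] - y[j];
    double wx = x[k] - x[j], wy = y[k] - y[j];
    double lu = std::sqrt(ux * ux + uyv * uyv);
    double lw = std::sqrt(wx * wx + wy * wy);
    if (lu <= 0.0 || lw <= 0.0)
      stop("zero-length arm in angle bond (%d, %d, %d)", i + 1, j + 1, k + 1);
    double ct = (ux * wx + uyv * wy) / (lu * lw);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    theta[m] = th;
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-16));
    double dU = 2.0 * ka[m] * (th - th0[m]);
    // dtheta/dr_i = -(w_hat - ct*u_hat) / (|u| st); likewise for k
    double gix = -(wx / lw - ct * ux / lu) / (lu * st);
    double giy = -(wy / lw - ct * uyv / lu) / (lu * st);
    double gkx = -(ux / lu - ct * wx / lw) / (lw * st);
    double gky = -(uyv / lu - ct * wy / lw) / (lw * st);
    double fxi = -dU * gix, fyi = -dU * giy;
    double fxk = -dU * gkx, fyk = -dU * gky;
    fx[i] += fxi; fy[i] += fyi;
    fx[k] += fxk; fy[k] += fyk;
    fx[j] -= fxi + fxk; fy[j] -= fyi + fyk; // translational invariance
  }
  return List::create(_["fx"] = fx, _["fy"] = fy, _["theta"] = theta);
}
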