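#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear spring-dashpot DEM contacts with Coulomb stick/slip tangential
// history. Caller supplies the currently overlapping pairs together with
// their ledger tangential displacement (xix, xiy), zero for new contacts.
// The normal force is clamped to be non-adhesive; the tangential spring is
// truncated to the Coulomb cone and the ledger displacement rescaled to the
// sliding value on the dynamic branch.
// (ux,uy) points from j to i; delta = overlap >= 0.
// [[Rcpp::export]]
List cpp_dem_forces(IntegerVector pi, IntegerVector pj, NumericVector delta,
                    NumericVector ux, NumericVector uy,
                    NumericVector m, NumericVector vx, NumericVector vy,
                    double kn, double gn, double kt, double gt,
                    double mus, double mud,
                    NumericVector xix, NumericVector xiy, double dt,
                    NumericVector scale, int n) {
  const int np = pi.size();
  NumericVector fx(n), fy(n), fnv(np), ftv(np);
  NumericVector xixn(np), xiyn(np);
  for (int k = 0; k < np; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double meff = m[i] * m[j] / (m[i] + m[j]);
    double vijx = vx[i] - vx[j], vijy = vy[i] - vy[j];
    double vn = vijx * ux[k] + vijy * uy[k]; // > 0 when separating
    double fn = kn * delta[k] + meff * gn * (-vn);
    if (fn < 0.0) fn = 0.0; // no adhesion from the dashpot at separation
    // tangent frame (right-handed): t = (-uy, ux)
    double tx = -uy[k], ty = ux[k];
    double vt = vijx * tx + vijy * ty;
    double xs = xix[k] * tx + xiy[k] * ty; // re-projected history
    xs += vt * dt;
    double ft = -kt * xs - meff * gt * vt;
    if (std::abs(ft) > mus * fn) { // dynamic branch
      double sgn = (ft >= 0.0) ? 1.0 : -1.0;
      ft = sgn * mud * fn;
      if (kt > 0.0) xs = -(ft + meff * gt * vt) / kt; // sliding value
    }
    double sc = scale[k % scale.size()];
    double fxk = sc * (fn * ux[k] + ft * tx);
    double fyk = sc * (fn * uy[k] + ft * ty);
    fx[i] += fxk; fy[i] += fyk;
    fx[j] -= fxk; fy[j] -= fyk;
    fnv[k] = fn; ftv[k] = ft;
    xixn[k] = xs * tx; xiyn[k] = xs * ty;
  }
  return List::create(_["fx"] = fx, _["fy"] = fy, _["fn"] = fnv,
                      _["ft"] = ftv, _["xix"] = xixn, _["xiy"] = xiyn);
}

// Lennard-Jones pair forces U = 4 eps [(sigma/r)^12 - (sigma/r)^6],
// truncated at rc. With rc = 2^(1/6) sigma (or rc = sigma) only the
// repulsive branch acts (no-penetration coupling); with rc = 2.5 sigma the
// attractive well models adhesion. eps may vary per pair (concentration-
// scaled adhesion). The magnitude is capped at fmax to keep over-penetrated
// pairs finite; the number of capped pairs is reported.
// [[Rcpp::export]]
List cpp_lj_forces(IntegerVector pi, IntegerVector pj, NumericVector r,
                   NumericVector ux, NumericVector uy, NumericVector eps,
                   double sigma, double rc, double fmax, int n) {
  const int np = pi.size();
  NumericVector fx(n), fy(n);
  int ncapped = 0;
  for (int k = 0; k < np; ++k) {
    if (r[k] >= rc) continue;
    double e = eps[k % eps.size()];
    if (e == 0.0) continue;
    int i = pi[k] - 1, j = pj[k] - 1;
    double sr6 = std::pow(sigma / r[k], 6.0);
    // -dU/dr, positive = repulsive (along +u, away from j)
    double f = 24.0 * e / r[k] * (2.0 * sr6 * sr6 - sr6);
    if (std::abs(f) > fmax) { f = (f > 0 ? fmax : -fmax); ++ncapped; }
    fx[i] += f * ux[k]; fy[i] += f * uy[k];
    fx[j] -= f * ux[k]; fy[j] -= f * uy[k];
  }
  return List::create(_["fx"] = fx, _["fy"] = fy, _["n_capped"] = ncapped);
}
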