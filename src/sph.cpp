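#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic-spline kernel, 2D normalization 10/(7*pi*h^2), support radius 2h.
static inline double w_cubic(double r, double h) {
  double q = r / h;
  if (q >= 2.0) return 0.0;
  double s = 10.0 / (7.0 * M_PI * h * h);
  if (q < 1.0) return s * (1.0 - 1.5 * q * q + 0.75 * q * q * q);
  double t = 2.0 - q;
  return s * 0.25 * t * t * t;
}

// dW/dr (negative for 0 < r < 2h)
static inline double dw_cubic(double r, double h) {
  double q = r / h;
  if (q >= 2.0) return 0.0;
  double s = 10.0 / (7.0 * M_PI * h * h * h);
  if (q < 1.0) return s * (-3.0 * q + 2.25 * q * q);
  double t = 2.0 - q;
  return s * (-0.75 * t * t);
}

// [[Rcpp::export]]
NumericVector cpp_kernel_w(NumericVector r, double h) {
  int n = r.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = w_cubic(r[k], h);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_kernel_dw(NumericVector r, double h) {
  int n = r.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = dw_cubic(r[k], h);
  return out;
}

// SPH momentum forces: symmetrized pressure term plus either Monaghan
// artificial viscosity (visc_type 1) or the Morris physical-viscosity
// pair term (visc_type 2); visc_type 0 disables viscosity, visc_type 3
// computes the viscous term only (ghost-value no-slip coupling against
// solid surfaces). `scale` is a per-pair blending weight.
// (ux,uy) is the unit vector from j to i, so grad_i W = dW * (ux,uy).
// [[Rcpp::export]]
List cpp_sph_forces(IntegerVector pi, IntegerVector pj, NumericVector r,
                    NumericVector ux, NumericVector uy,
                    NumericVector m, NumericVector rho, NumericVector P,
                    NumericVector vx, NumericVector vy,
                    double h, int visc_type, double alpha, double c0,
                    NumericVector mu, NumericVector scale, int n) {
  const int np = pi.size();
  NumericVector fx(n), fy(n);
  const double eps_h2 = 0.01 * h * h;
  for (int k = 0; k < np; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    if (rho[i] <= 0.0 || rho[j] <= 0.0)
      stop("zero or negative density in SPH pair (%d, %d)", i + 1, j + 1);
    double dw = dw_cubic(r[k], h);
    if (dw == 0.0) continue;
    double sc = scale[k % scale.size()];
    double fxk = 0.0, fyk = 0.0;
    double vijx = vx[i] - vx[j], vijy = vy[i] - vy[j];
    if (visc_type != 3) {
      double bracket = P[i] / (rho[i] * rho[i]) + P[j] / (rho[j] * rho[j]);
      if (visc_type == 1) { // Monaghan artificial viscosity
        double vr = vijx * ux[k] + vijy * uy[k];
        if (vr < 0.0) {
          double muij = h * vr * r[k] / (r[k] * r[k] + eps_h2);
          double rhobar = 0.5 * (rho[i] + rho[j]);
          bracket += -alpha * c0 * muij / rhobar;
        }
      }
      double f = -m[i] * m[j] * bracket * dw; // along +u: repulsive for P > 0
      fxk += f * ux[k];
      fyk += f * uy[k];
    }
    if (visc_type == 2 || visc_type == 3) { // Morris viscous term
      double coef = m[i] * m[j] * (mu[i] + mu[j]) / (rho[i] * rho[j]) *
        (r[k] * dw) / (r[k] * r[k] + eps_h2);
      fxk += coef * vijx; // coef < 0: damps relative motion
      fyk += coef * vijy;
    }
    fx[i] += sc * fxk; fy[i] += sc * fyk;
    fx[j] -= sc * fxk; fy[j] -= sc * fyk;
  }
  return List::create(_["fx"] = fx, _["fy"] = fy);
}

// Continuity equation: drho_i/dt = sum_j m_j (v_i - v_j) . grad_i W_ij
// [[Rcpp::export]]
NumericVector cpp_continuity(IntegerVector pi, IntegerVector pj,
                             NumericVector r, NumericVector ux,
                             NumericVector uy, NumericVector m,
                             NumericVector vx, NumericVector vy,
                             double h, NumericVector scale, int n) {
  const int np = pi.size();
  NumericVector drho(n);
  for (int k = 0; k < np; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double dw = dw_cubic(r[k], h);
    if (dw == 0.0) continue;
    double sc = scale[k % scale.size()];
    double vr = (vx[i] - vx[j]) * ux[k] + (vy[i] - vy[j]) * uy[k];
    drho[i] += sc * m[j] * vr * dw;
    drho[j] += sc * m[i] * vr * dw;
  }
  return drho;
}

// Shared pair-summation for SPH scalar transport (heat conduction and
// solute diffusion). Returns the extensive rate
//   Q_i = sum_j m_i m_j / (rho_i rho_j) (k_i + k_j) (f_i - f_j) G_ij
// with G_ij = (r_ij . grad_i W) / r^2 = dW/r < 0, so Q is antisymmetric
// pairwise and the field flows downhill. Divide by m_i for a per-mass rate.
// [[Rcpp::export]]
NumericVector cpp_pair_laplacian(IntegerVector pi, IntegerVector pj,
                                 NumericVector r, NumericVector m,
                                 NumericVector rho, NumericVector coef,
                                 NumericVector field, double h, int n) {
  const int np = pi.size();
  NumericVector Q(n);
  for (int k = 0; k < np; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double cc = coef[i] + coef[j];
    if (cc == 0.0) continue;
    double dw = dw_cubic(r[k], h);
    if (dw == 0.0) continue;
    double G = dw / r[k];
    double q = m[i] * m[j] / (rho[i] * rho[j]) * cc * (field[i] - field[j]) * G;
    Q[i] += q;
    Q[j] -= q;
  }
  return Q;
}

// Summation density: rho_i = sum_j m_j W_ij (including self term).
// [[Rcpp::export]]
NumericVector cpp_summation_density(IntegerVector pi, IntegerVector pj,
                                    NumericVector r, NumericVector m,
                                    double h, int n) {
  const int np = pi.size();
  NumericVector rho(n);
  for (int i = 0; i < n; ++i) rho[i] = m[i] * w_cubic(0.0, h);
  for (int k = 0; k < np; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double w = w_cubic(r[k], h);
    rho[i] += m[j] * w;
    rho[j] += m[i] * w;
  }
  return rho;
}

// Shepard-filtered summation density: rho_i = sum m_j W_ij / sum (m_j/rho_j) W_ij
// (self terms included). Normalizes out kernel deficiency at boundaries,
// so it can reinitialize the continuity-evolved field everywhere.
// [[Rcpp::export]]
NumericVector cpp_shepard_density(IntegerVector pi, IntegerVector pj,
                                  NumericVector r, NumericVector m,
                                  NumericVector rho, double h, int n) {
  const int np = pi.size();
  NumericVector num(n), den(n);
  double w0 = w_cubic(0.0, h);
  for (int i = 0; i < n; ++i) {
    num[i] = m[i] * w0;
    den[i] = m[i] / rho[i] * w0;
  }
  for (int k = 0; k < np; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double w = w_cubic(r[k], h);
    num[i] += m[j] * w;       den[i] += m[j] / rho[j] * w;
    num[j] += m[i] * w;       den[j] += m[i] / rho[i] * w;
  }
  for (int i = 0; i < n; ++i) num[i] /= den[i];
  return num;
}

// Coordination number: neighbors within `cutoff` (surface detection).
// [[Rcpp::export]]
IntegerVector cpp_coordination(IntegerVector pi, IntegerVector pj,
                               NumericVector r, double cutoff, int n) {
  const int np = pi.size();
  IntegerVector coord(n);
  for (int k = 0; k < np; ++k) {
    if (r[k] <= cutoff) {
      coord[pi[k] - 1] += 1;
      coord[pj[k] - 1] += 1;
    }
  }
  return coord;
}
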