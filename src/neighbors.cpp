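#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum-image displacement on one axis.
static inline double min_image(double d, double L, bool periodic) {
  if (periodic) {
    if (d > 0.5 * L) d -= L;
    else if (d < -0.5 * L) d += L;
  }
  return d;
}

// Cell-binned neighbor search with optional periodic axes.
// Returns pairs stored once with i < j (1-based), the separation distance,
// and the unit vector pointing from j to i (minimum image).
// [[Rcpp::export]]
List cpp_neighbor_list(NumericVector x, NumericVector y, double cutoff,
                       double xlo, double xhi, double ylo, double yhi,
                       bool perx, bool pery) {
  const int n = x.size();
  if (cutoff <= 0.0) stop("cutoff must be > 0");
  for (int i = 0; i < n; ++i) {
    if (!R_finite(x[i]) || !R_finite(y[i]))
      stop("non-finite position for particle %d", i + 1);
  }
  const double Lx = xhi - xlo, Ly = yhi - ylo;
  const double c2 = cutoff * cutoff;

  std::vector<int> pi, pj;
  std::vector<double> pr, pux, puy;
  pi.reserve(16 * n); pj.reserve(16 * n);
  pr.reserve(16 * n); pux.reserve(16 * n); puy.reserve(16 * n);

  int ncx = std::max(1, (int)std::floor(Lx / cutoff));
  int ncy = std::max(1, (int)std::floor(Ly / cutoff));
  bool brute = (perx && ncx < 3) || (pery && ncy < 3) || (n < 64);

  auto push_pair = [&](int i, int j) {
    double dx = min_image(x[i] - x[j], Lx, perx);
    double dy = min_image(y[i] - y[j], Ly, pery);
    double r2 = dx * dx + dy * dy;
    if (r2 <= c2 && r2 > 0.0) {
      double r = std::sqrt(r2);
      pi.push_back(i + 1); pj.push_back(j + 1);
      pr.push_back(r); pux.push_back(dx / r); puy.push_back(dy / r);
    }
  };

  if (brute) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) push_pair(i, j);
  } else {
    // bin particles; non-periodic axes may have positions outside the
    // nominal bounds (free surfaces), so clamp the cell index
    std::vector<int> head(ncx * ncy, -1), nxt(n, -1);
    std::vector<int> cxv(n), cyv(n);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor((x[i] - xlo) / Lx * ncx);
      int cy = (int)std::floor((y[i] - ylo) / Ly * ncy);
      if (perx) cx = ((cx % ncx) + ncx) % ncx; else cx = std::min(std::max(cx, 0), ncx - 1);
      if (pery) cy = ((cy % ncy) + ncy) % ncy; else cy = std::min(std::max(cy, 0), ncy - 1);
      cxv[i] = cx; cyv[i] = cy;
      int c = cy * ncx + cx;
      nxt[i] = head[c]; head[c] = i;
    }
    for (int i = 0; i < n; ++i) {
      for (int ox = -1; ox <= 1; ++ox) {
        for (int oy = -1; oy <= 1; ++oy) {
          int cx = cxv[i] + ox, cy = cyv[i] + oy;
          if (perx) cx = ((cx % ncx) + ncx) % ncx;
          else if (cx < 0 || cx >= ncx) continue;
          if (pery) cy = ((cy % ncy) + ncy) % ncy;
          else if (cy < 0 || cy >= ncy) continue;
          for (int j = head[cy * ncx + cx]; j >= 0; j = nxt[j]) {
            if (j > i) push_pair(i, j);
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["r"] = wrap(pr), _["ux"] = wrap(pux),
                      _["uy"] = wrap(puy));
}
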