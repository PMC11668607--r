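#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Inverse-distance-weighted prediction of one or more variables at a set
// of target locations.
//
// For each target, the N nearest sources within maxRadius are found
// (N = 0 means all sources), weights d^-p are normalised to sum to one,
// and each variable's prediction is the weighted average of the source
// values.  A source closer than zeroTol metres short-circuits to an exact
// return of that source's value (exact-interpolator convention).  Ties at
// the N-th neighbour distance are broken by the lower tieKey (shot id).
// Targets with no source in radius get NA.
//
// [[Rcpp::export(name = ".idwCore")]]
NumericMatrix idwCore(NumericVector tx, NumericVector ty,
                      NumericVector sx, NumericVector sy,
                      NumericMatrix values, IntegerVector tieKey,
                      double power, int nNeighbors, double maxRadius,
                      double zeroTol) {
  const int nt = tx.size();
  const int ns = sx.size();
  const int nv = values.ncol();
  NumericMatrix out(nt, nv);
  const bool limited = nNeighbors > 0 && nNeighbors < ns;
  const double maxR2 = R_FINITE(maxRadius) ? maxRadius * maxRadius
                                           : R_PosInf;

  struct Cand { double d2; int key; int idx; };
  std::vector<Cand> cand;
  cand.reserve(ns);

  for (int t = 0; t < nt; ++t) {
    cand.clear();
    int exact = -1;
    for (int s = 0; s < ns; ++s) {
      const double dx = sx[s] - tx[t];
      const double dy = sy[s] - ty[t];
      const double d2 = dx * dx + dy * dy;
      if (d2 < zeroTol * zeroTol) { exact = s; break; }
      if (d2 <= maxR2) cand.push_back({d2, tieKey[s], s});
    }
    if (exact >= 0) {
      for (int v = 0; v < nv; ++v) out(t, v) = values(exact, v);
      continue;
    }
    if (cand.empty()) {
      for (int v = 0; v < nv; ++v) out(t, v) = NA_REAL;
      continue;
    }
    size_t use = cand.size();
    if (limited && (size_t)nNeighbors < cand.size()) {
      use = (size_t)nNeighbors;
      std::nth_element(cand.begin(), cand.begin() + use - 1, cand.end(),
                       [](const Cand &a, const Cand &b) {
                         if (a.d2 != b.d2) return a.d2 < b.d2;
                         return a.key < b.key;
                       });
    }
    double wsum = 0.0;
    std::vector<double> acc(nv, 0.0);
    for (size_t i = 0; i < use; ++i) {
      const double w = std::pow(cand[i].d2, -power / 2.0);
      wsum += w;
      for (int v = 0; v < nv; ++v) acc[v] += w * values(cand[i].idx, v);
    }
    for (int v = 0; v < nv; ++v) out(t, v) = acc[v] / wsum;
  }
  return out;
}
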