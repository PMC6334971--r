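#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// CLANS-style force-directed 2D embedding.
//
// Per iteration: attractive force along each kept edge with magnitude
// attraction * distance, pairwise repulsion with magnitude 1/distance,
// simultaneous damped update with cooling (step = step0 * decay^iter, the
// per-node displacement is clipped to the current step so strong edges
// cannot catapult nodes).  Coordinates depend on pairwise differences only,
// so the embedding is translation-equivariant in its initial coordinates.
//
// init: n x 2 starting coordinates; ei/ej: 0-based edge endpoints.

// [[Rcpp::export(name = ".clansLayoutC")]]
NumericMatrix clansLayoutC(NumericMatrix init, IntegerVector ei,
                           IntegerVector ej, NumericVector att,
                           int nIter, double step0, double decay) {
  const int n = init.nrow(), ne = ei.size();
  NumericMatrix xy(clone(init));
  std::vector<double> fx(n), fy(n);
  double step = step0;
  const double eps = 1e-9;
  for (int it = 0; it < nIter; ++it) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      const int a = ei[e], b = ej[e];
      const double dx = xy(b, 0) - xy(a, 0), dy = xy(b, 1) - xy(a, 1);
      fx[a] += att[e] * dx; fy[a] += att[e] * dy;
      fx[b] -= att[e] * dx; fy[b] -= att[e] * dy;
    }
    for (int a = 0; a < n; ++a) {
      for (int b = a + 1; b < n; ++b) {
        double dx = xy(b, 0) - xy(a, 0), dy = xy(b, 1) - xy(a, 1);
        double d2 = dx * dx + dy * dy;
        if (d2 < eps) d2 = eps;
        // magnitude 1/d in direction away from the other node
        fx[a] -= dx / d2; fy[a] -= dy / d2;
        fx[b] += dx / d2; fy[b] += dy / d2;
      }
    }
    for (int a = 0; a < n; ++a) {
      double mx = step * fx[a], my = step * fy[a];
      const double norm = std::sqrt(mx * mx + my * my);
      if (norm > step) { mx *= step / norm; my *= step / norm; }
      xy(a, 0) += mx; xy(a, 1) += my;
    }
    step *= decay;
  }
  return xy;
}
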