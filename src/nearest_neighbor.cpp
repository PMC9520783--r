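#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive nearest-neighbour lookup from each source row to the target
// rows. Ties are broken towards the lowest target index (strict < while
// scanning in ascending order), which keeps runs deterministic.
// [[Rcpp::export]]
List nn_bruteforce(NumericMatrix source, NumericMatrix target) {
  const int n = source.nrow();
  const int m = target.nrow();
  IntegerVector index(n);
  NumericVector distance(n);
  for (int i = 0; i < n; ++i) {
    const double sx = source(i, 0), sy = source(i, 1), sz = source(i, 2);
    double best = R_PosInf;
    int best_j = -1;
    for (int j = 0; j < m; ++j) {
      const double dx = target(j, 0) - sx;
      const double dy = target(j, 1) - sy;
      const double dz = target(j, 2) - sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        best_j = j;
      }
    }
    index[i] = best_j + 1;  // 1-based for R
    distance[i] = std::sqrt(best);
  }
  return List::create(_["index"] = index, _["distance"] = distance);
}
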