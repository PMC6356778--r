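// Greedy left-to-right LD pruning on a dosage matrix.
// A candidate site is dropped when its squared Pearson correlation
// (pairwise-complete) with any of the last `window` retained sites exceeds
// the threshold.  Counting the window over retained sites makes the
// operation idempotent: re-running on its own output compares exactly the
// same pairs and changes nothing.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// dos: sites x individuals, NA for missing
// [[Rcpp::export(name = ".cpp_ld_prune")]]
LogicalVector cpp_ld_prune(IntegerMatrix dos, double r2max, int window) {
  const int S = dos.nrow(), N = dos.ncol();
  LogicalVector keep(S);
  std::vector<int> kept;  // row indices of retained sites
  kept.reserve(S);
  for (int j = 0; j < S; ++j) {
    bool drop = false;
    const int tMin = std::max(0, (int)kept.size() - window);
    for (int t = (int)kept.size() - 1; t >= tMin && !drop; --t) {
      int i = kept[t];
      // pairwise-complete r^2
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0; int n = 0;
      for (int c = 0; c < N; ++c) {
        int x = dos(i, c), y = dos(j, c);
        if (x == NA_INTEGER || y == NA_INTEGER) continue;
        ++n; sx += x; sy += y; sxx += (double)x * x; syy += (double)y * y; sxy += (double)x * y;
      }
      if (n < 2) continue;
      double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
      if (vx <= 0 || vy <= 0) continue;  // monomorphic in overlap: undefined, keep
      double cv = sxy - sx * sy / n;
      double r2 = (cv * cv) / (vx * vy);
      if (r2 > r2max) drop = true;
    }
    keep[j] = !drop;
    if (!drop) kept.push_back(j);
  }
  return keep;
}
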