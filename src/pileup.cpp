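// Pileup accumulation for one individual: per-site base counts from uniquely
// mapped reads.  Returns total depth per reference position plus a sparse
// list of non-reference base observations.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}
static inline char complB(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// reads: query sequences as given to the mapper; start1: 1-based leftmost
// alignment position (NA = skip); strand: +1/-1 (minus-strand reads are
// reverse complemented before stacking, matching the aligned orientation).
// [[Rcpp::export(name = ".cpp_pileup_counts")]]
List cpp_pileup_counts(std::string ref, CharacterVector reads,
                       IntegerVector start1, IntegerVector strand) {
  const int L = (int)ref.size();
  std::vector<unsigned int> cnt((size_t)L * 4, 0u);
  for (int i = 0; i < reads.size(); ++i) {
    if (start1[i] == NA_INTEGER) continue;
    std::string q = as<std::string>(reads[i]);
    const int m = (int)q.size();
    int st = start1[i] - 1;
    if (st < 0 || st + m > L) stop("alignment outside reference");
    if (strand[i] == -1) {
      std::string r(q.rbegin(), q.rend());
      for (int j = 0; j < m; ++j) r[j] = complB(r[j]);
      q = r;
    }
    for (int j = 0; j < m; ++j) {
      int c = code(q[j]);
      if (c >= 0) cnt[(size_t)(st + j) * 4 + c]++;
    }
  }
  IntegerVector depth(L);
  std::vector<int> mpos, mbase, mcnt;
  for (int p = 0; p < L; ++p) {
    int rc = code(ref[p]);
    unsigned int d = 0;
    for (int b = 0; b < 4; ++b) {
      unsigned int c = cnt[(size_t)p * 4 + b];
      d += c;
      if (c > 0 && b != rc) { mpos.push_back(p + 1); mbase.push_back(b); mcnt.push_back((int)c); }
    }
    depth[p] = (int)d;
  }
  return List::create(_["depth"] = depth, _["pos"] = wrap(mpos),
                      _["base"] = wrap(mbase), _["count"] = wrap(mcnt));
}
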