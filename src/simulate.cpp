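// Sequencing-read simulation kernels.  All randomness comes from R's RNG
// (unif_rand / R::rpois / R::rbinom) so results are governed by set.seed().

#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char complBase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcompStr(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = complBase(r[i]);
  return r;
}

// substitute sequencing errors in place; each error picks a different base
static void addErrors(std::string& s, double errRate) {
  int nerr = (int)R::rbinom((double)s.size(), errRate);
  for (int e = 0; e < nerr; ++e) {
    int p = (int)(unif_rand() * s.size());
    if (p >= (int)s.size()) p = (int)s.size() - 1;
    char old = s[p];
    char nb;
    do { nb = BASES[(int)(unif_rand() * 4) & 3]; } while (nb == old);
    s[p] = nb;
  }
}

// Build one individual's haplotype sequence: reference with alt alleles applied.
static std::string applyVariants(const std::string& ref, IntegerVector pos0,
                                 CharacterVector alt) {
  std::string h = ref;
  for (int i = 0; i < pos0.size(); ++i) {
    int p = pos0[i];
    if (p >= 0 && p < (int)h.size()) h[p] = CHAR(STRING_ELT(alt, i))[0];
  }
  return h;
}

// Paired-end resequencing reads for one individual.
// posA/altA and posB/altB: 0-based positions and alt bases on each haplotype.
// [[Rcpp::export(name = ".cpp_simulate_read_pairs")]]
List cpp_simulate_read_pairs(std::string ref,
                             IntegerVector posA, CharacterVector altA,
                             IntegerVector posB, CharacterVector altB,
                             int nPairs, int readLen, int fragLen,
                             double errRate) {
  RNGScope rng;
  if (fragLen < readLen) stop("fragment shorter than read length");
  const int L = (int)ref.size();
  if (L < fragLen) stop("genome shorter than fragment length");
  std::string hapA = applyVariants(ref, posA, altA);
  std::string hapB = applyVariants(ref, posB, altB);
  CharacterVector fwd(nPairs), rev(nPairs);
  IntegerVector start(nPairs), hap(nPairs);
  for (int i = 0; i < nPairs; ++i) {
    int st = (int)(unif_rand() * (L - fragLen + 1));
    if (st > L - fragLen) st = L - fragLen;
    bool useB = unif_rand() < 0.5;
    const std::string& h = useB ? hapB : hapA;
    std::string f = h.substr(st, readLen);
    std::string r = revcompStr(h.substr(st + fragLen - readLen, readLen));
    if (errRate > 0) { addErrors(f, errRate); addErrors(r, errRate); }
    fwd[i] = f; rev[i] = r;
    start[i] = st + 1;            // 1-based fragment start
    hap[i] = useB ? 2 : 1;
  }
  return List::create(_["fwd"] = fwd, _["rev"] = rev,
                      _["start"] = start, _["hap"] = hap);
}

// GBS tag pairs for one individual.  cutPos0: 0-based motif start positions
// on the focal genome.  The forward tag reads rightwards from the cut site;
// the reverse tag is the reverse complement of the window ending at the end
// of the recognition motif (both "start at the cut site" from opposite
// sides).  Reads per locus ~ Poisson(meanDepth); each read samples one
// haplotype; per-base errors at errRate.  Identical (fwd, rev) pairs are
// aggregated with counts.
// [[Rcpp::export(name = ".cpp_simulate_tag_pairs")]]
List cpp_simulate_tag_pairs(std::string ref,
                            IntegerVector posA, CharacterVector altA,
                            IntegerVector posB, CharacterVector altB,
                            IntegerVector cutPos0, int tagLen, int motifLen,
                            double meanDepth, double errRate) {
  RNGScope rng;
  const int L = (int)ref.size();
  std::string hapA = applyVariants(ref, posA, altA);
  std::string hapB = applyVariants(ref, posB, altB);
  std::vector<int> outLocus;
  std::vector<std::string> outFwd, outRev;
  std::vector<int> outCount;
  std::vector<int> skipped;
  for (int li = 0; li < cutPos0.size(); ++li) {
    int p = cutPos0[li];
    if (p + tagLen > L || p + motifLen - tagLen < 0) { skipped.push_back(li + 1); continue; }
    int n = (int)R::rpois(meanDepth);
    if (n <= 0) continue;
    int nA = (int)R::rbinom((double)n, 0.5);
    std::string fwdH[2], revH[2];
    fwdH[0] = hapA.substr(p, tagLen);
    revH[0] = revcompStr(hapA.substr(p + motifLen - tagLen, tagLen));
    fwdH[1] = hapB.substr(p, tagLen);
    revH[1] = revcompStr(hapB.substr(p + motifLen - tagLen, tagLen));
    std::map<std::pair<std::string, std::string>, int> tally;
    for (int h = 0; h < 2; ++h) {
      int nh = h == 0 ? nA : n - nA;
      for (int r = 0; r < nh; ++r) {
        std::string f = fwdH[h], v = revH[h];
        if (errRate > 0) { addErrors(f, errRate); addErrors(v, errRate); }
        tally[std::make_pair(f, v)]++;
      }
    }
    for (auto& kv : tally) {
      outLocus.push_back(li + 1);       // 1-based index into cutPos
      outFwd.push_back(kv.first.first);
      outRev.push_back(kv.first.second);
      outCount.push_back(kv.second);
    }
  }
  return List::create(_["locus"] = wrap(outLocus), _["fwd"] = wrap(outFwd),
                      _["rev"] = wrap(outRev), _["count"] = wrap(outCount),
                      _["skippedLoci"] = wrap(skipped));
}
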