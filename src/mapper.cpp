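// Deterministic seed-and-extend read mapper with exhaustive sensitivity.
//
// Candidate positions come from exact seed hits in a k-mer index; each
// candidate is extended ungapped over the full query and scored by Hamming
// distance.  Sensitivity is guaranteed by a two-round pigeonhole scheme:
//   round 1: disjoint seeds of length k1 (default min(seed_length, 12));
//            s1 = floor(m / k1) disjoint seeds find every hit with
//            mismatches < s1.
//   round 2 (only if round 1 cannot certify the best hit): disjoint seeds of
//            length k2 = floor(m / (maxmm + 1)); since s2 = floor(m / k2)
//            >= maxmm + 1, every hit with <= maxmm mismatches shares at
//            least one exact seed, so the result equals a brute-force scan
//            of every offset on both strands.
// Equal-best hits at distinct (position, strand) make the query ambiguous.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <climits>
#include <memory>
using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N'; break;
    }
  }
  return r;
}

struct KmerIndex {
  int k = 0;
  std::vector<int> bucket;  // 4^k + 1 offsets
  std::vector<int> pos;     // positions grouped by k-mer value
  void build(const std::string& ref, int kk) {
    k = kk;
    const int L = (int)ref.size();
    const size_t nb = ((size_t)1) << (2 * k);
    const unsigned mask = (unsigned)(nb - 1);
    std::vector<int> kmerAt(L >= k ? L - k + 1 : 0, -1);
    unsigned val = 0; int run = 0;
    for (int i = 0; i < L; ++i) {
      int c = baseCode(ref[i]);
      if (c < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (unsigned)c) & mask;
      if (++run >= k) kmerAt[i - k + 1] = (int)val;
    }
    bucket.assign(nb + 1, 0);
    for (size_t i = 0; i < kmerAt.size(); ++i)
      if (kmerAt[i] >= 0) bucket[(size_t)kmerAt[i] + 1]++;
    for (size_t b = 1; b <= nb; ++b) bucket[b] += bucket[b - 1];
    pos.assign(bucket[nb], 0);
    std::vector<int> fill(bucket.begin(), bucket.end() - 1);
    for (size_t i = 0; i < kmerAt.size(); ++i)
      if (kmerAt[i] >= 0) pos[fill[kmerAt[i]]++] = (int)i;
  }
};

struct RefIndex {
  std::string ref;
  int k1 = 0;
  KmerIndex idx1;
  // escalation indexes built lazily, keyed by k
  std::vector<std::unique_ptr<KmerIndex>> small;  // index by k (size 16)
  RefIndex() : small(16) {}
  KmerIndex* getSmall(int k) {
    if (k < 2) k = 2;
    if (k > 12) k = 12;
    if (!small[k]) { small[k].reset(new KmerIndex()); small[k]->build(ref, k); }
    return small[k].get();
  }
};

// [[Rcpp::export(name = ".cpp_build_ref_index")]]
SEXP cpp_build_ref_index(std::string refseq, int seedLen) {
  RefIndex* ri = new RefIndex();
  ri->ref = refseq;
  ri->k1 = std::min(seedLen, 12);
  if (ri->k1 < 2) ri->k1 = 2;
  ri->idx1.build(ri->ref, ri->k1);
  XPtr<RefIndex> p(ri, true);
  return p;
}

// Collect candidate (start, strand) pairs from exact seed hits.
static void collectCandidates(const KmerIndex& idx, const std::string& ref,
                              const std::string& q, int strand,
                              std::vector<int64_t>& cand) {
  const int m = (int)q.size();
  const int k = idx.k;
  if (k > m) return;
  const int L = (int)ref.size();
  const size_t nb = ((size_t)1) << (2 * k);
  const unsigned mask = (unsigned)(nb - 1);
  for (int off = 0; off + k <= m; off += k) {
    unsigned val = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = baseCode(q[off + j]);
      if (c < 0) { ok = false; break; }
      val = ((val << 2) | (unsigned)c) & mask;
    }
    if (!ok) continue;
    int b0 = idx.bucket[val], b1 = idx.bucket[val + 1];
    for (int b = b0; b < b1; ++b) {
      int start = idx.pos[b] - off;
      if (start >= 0 && start + m <= L)
        cand.push_back(((int64_t)start << 1) | strand);
    }
  }
}

// Hamming distance with early abort above cap; returns cap + 1 when exceeded.
static inline int hammingCapped(const std::string& ref, int start,
                                const std::string& q, int cap) {
  int mm = 0;
  const int m = (int)q.size();
  for (int j = 0; j < m; ++j) {
    if (ref[start + j] != q[j]) {
      if (++mm > cap) return cap + 1;
    }
  }
  return mm;
}

struct BestHit {
  int mm = INT_MAX;
  int nbest = 0;
  int start = -1;
  int strand = 0;
  void consider(int mmi, int st, int sd) {
    if (mmi < mm) { mm = mmi; nbest = 1; start = st; strand = sd; }
    else if (mmi == mm) { nbest++; }
  }
};

static void scoreCandidates(const std::string& ref, const std::string& qf,
                            const std::string& qr, std::vector<int64_t>& cand,
                            int maxmm, BestHit& best) {
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (int64_t c : cand) {
    int strand = (int)(c & 1);
    int start = (int)(c >> 1);
    const std::string& q = strand ? qr : qf;
    int mm = hammingCapped(ref, start, q, maxmm);
    if (mm <= maxmm) best.consider(mm, start, strand);
  }
}

static inline int maxMismatches(int m, double frac) {
  return (int)std::ceil(frac * m - 1e-9);
}

// [[Rcpp::export(name = ".cpp_map_batch")]]
List cpp_map_batch(SEXP indexPtr, CharacterVector queries, double maxFrac) {
  XPtr<RefIndex> ri(indexPtr);
  const std::string& ref = ri->ref;
  const int n = queries.size();
  IntegerVector status(n), start(n), strand(n), nm(n);
  std::vector<int64_t> cand;
  for (int i = 0; i < n; ++i) {
    std::string qf = as<std::string>(queries[i]);
    const int m = (int)qf.size();
    if (m < 4) stop("query shorter than 4 bp");
    const int maxmm = maxMismatches(m, maxFrac);
    std::string qr = revcomp(qf);
    BestHit best;

    // round 1: primary seeds
    int s1 = (ri->k1 <= m) ? m / ri->k1 : 0;
    if (s1 > 0) {
      cand.clear();
      collectCandidates(ri->idx1, ref, qf, 0, cand);
      collectCandidates(ri->idx1, ref, qr, 1, cand);
      scoreCandidates(ref, qf, qr, cand, maxmm, best);
    }
    // Round 1 finds every hit with mm < s1 (pigeonhole on disjoint seeds).
    // If the best found satisfies mm < s1, all equal-or-better hits were seen
    // (ties included); if nothing was found and maxmm < s1, no acceptable hit
    // exists.  Otherwise escalate.
    bool certified = (best.nbest > 0) ? (best.mm < s1) : (maxmm < s1);
    if (!certified) {
      int k2 = m / (maxmm + 1);
      if (k2 < 2)
        stop("mismatch allowance too high for query length (pigeonhole seeds < 2 bp)");
      KmerIndex* idx2 = ri->getSmall(std::min(k2, 12));
      cand.clear();
      collectCandidates(*idx2, ref, qf, 0, cand);
      collectCandidates(*idx2, ref, qr, 1, cand);
      best = BestHit();
      scoreCandidates(ref, qf, qr, cand, maxmm, best);
    }

    if (best.nbest == 0 || best.mm > maxmm) {
      status[i] = 0; start[i] = NA_INTEGER; strand[i] = NA_INTEGER; nm[i] = NA_INTEGER;
    } else if (best.nbest == 1) {
      status[i] = 1; start[i] = best.start; strand[i] = best.strand ? -1 : 1; nm[i] = best.mm;
    } else {
      status[i] = 2; start[i] = NA_INTEGER; strand[i] = NA_INTEGER; nm[i] = best.mm;
    }
  }
  return List::create(_["status"] = status, _["start"] = start,
                      _["strand"] = strand, _["nm"] = nm);
}

// Brute-force oracle: every offset, both strands, Hamming distance.
// Deliberately shares no candidate-generation machinery with the mapper.
// [[Rcpp::export(name = ".cpp_brute_map")]]
List cpp_brute_map(std::string ref, CharacterVector queries, double maxFrac) {
  const int L = (int)ref.size();
  const int n = queries.size();
  IntegerVector status(n), start(n), strand(n), nm(n);
  for (int i = 0; i < n; ++i) {
    std::string qf = as<std::string>(queries[i]);
    std::string qr = revcomp(qf);
    const int m = (int)qf.size();
    const int maxmm = maxMismatches(m, maxFrac);
    int bmm = maxmm + 1, nb = 0, bst = -1, bsd = 0;
    for (int sd = 0; sd < 2; ++sd) {
      const std::string& q = sd ? qr : qf;
      for (int st = 0; st + m <= L; ++st) {
        int mm = 0; bool over = false;
        for (int j = 0; j < m; ++j) {
          if (ref[st + j] != q[j] && ++mm > maxmm) { over = true; break; }
        }
        if (over) continue;
        if (mm < bmm) { bmm = mm; nb = 1; bst = st; bsd = sd; }
        else if (mm == bmm) { nb++; }
      }
    }
    if (nb == 0) {
      status[i] = 0; start[i] = NA_INTEGER; strand[i] = NA_INTEGER; nm[i] = NA_INTEGER;
    } else if (nb == 1) {
      status[i] = 1; start[i] = bst; strand[i] = bsd ? -1 : 1; nm[i] = bmm;
    } else {
      status[i] = 2; start[i] = NA_INTEGER; strand[i] = NA_INTEGER; nm[i] = bmm;
    }
  }
  return List::create(_["status"] = status, _["start"] = start,
                      _["strand"] = strand, _["nm"] = nm);
}
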