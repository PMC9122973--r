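// Canonical k-mer hashing and windowed read classification.
//
// Hashes are 2-bit packed (A=0 C=1 G=2 T=3), canonical = min(forward,
// reverse-complement), returned as doubles; k is capped at 26 so the hash
// (4^26 < 2^53) stays exactly representable.  Positions whose k-mer
// contains a non-ACGT base yield no hash.

#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// emit canonical hashes with their start offsets via callback-style loop
template <typename F>
static void canonical_scan(const std::string &s, int k, F emit) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      emit((long)(i + 1 - k), canon);
    }
  }
}

// [[Rcpp::export]]
NumericVector c_kmer_set(std::string seq, int k) {
  if (k < 2 || k > 26) stop("k must be in [2, 26]");
  std::unordered_set<uint64_t> set;
  canonical_scan(seq, k, [&](long, uint64_t h) { set.insert(h); });
  NumericVector out(set.size());
  size_t j = 0;
  for (uint64_t h : set) out[j++] = (double)h;
  std::sort(out.begin(), out.end());
  return out;
}

// Per-window component votes for a batch of reads.
// sets: list of numeric hash vectors (one per reference component); one
// combined hash->component-bitmask map gives a single lookup per k-mer.
// Returns a list of integer matrices (n_windows x n_components).
// [[Rcpp::export]]
List c_window_votes(CharacterVector reads, int k, int window, List sets) {
  if (k < 2 || k > 26) stop("k must be in [2, 26]");
  if (window < k) stop("window must be >= k");
  int ncomp = sets.size();
  if (ncomp > 8) stop("at most 8 components supported");
  std::unordered_map<uint64_t, uint8_t> comp;
  for (int j = 0; j < ncomp; ++j) {
    NumericVector v = sets[j];
    for (double x : v) comp[(uint64_t)x] |= (uint8_t)(1 << j);
  }
  List out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    int nwin = std::max(1, (int)((s.size() + window - 1) / window));
    IntegerMatrix votes(nwin, ncomp);
    int *vp = INTEGER(votes);
    canonical_scan(s, k, [&](long pos, uint64_t h) {
      auto it = comp.find(h);
      if (it == comp.end()) return;
      int w = (int)(pos / window);
      if (w >= nwin) w = nwin - 1;
      uint8_t m = it->second;
      for (int j = 0; j < ncomp; ++j) {
        if (m & (1 << j)) vp[w + (long)j * nwin]++;
      }
    });
    out[r] = votes;
  }
  return out;
}

// Offsets (0-based) at which each of `kmers` occurs exactly in `seq`,
// forward strand only; used for diagnostic-site anchoring.
// [[Rcpp::export]]
List c_exact_hits(std::string seq, CharacterVector kmers) {
  List out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    std::string p = as<std::string>(kmers[i]);
    std::vector<int> hits;
    size_t from = 0;
    while (true) {
      size_t at = seq.find(p, from);
      if (at == std::string::npos) break;
      hits.push_back((int)at);
      from = at + 1;
    }
    out[i] = wrap(hits);
  }
  return out;
}
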