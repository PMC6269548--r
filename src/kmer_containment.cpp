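#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode A/C/G/T; returns 4 for anything else.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// Enumerate canonical k-mers (min of forward and reverse-complement 2-bit
// encodings) of one sequence into `out`. k must be <= 32 so a k-mer fits in
// 64 bits. K-mers touching a non-ACGT character are skipped.
static void collect_canonical(const std::string& s, int k,
                              std::unordered_set<uint64_t>& out) {
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    const int c = base_code(s[i]);
    if (c == 4) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) out.insert(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export(name = ".kmer_containment")]]
NumericVector kmer_containment(CharacterVector sample_seqs,
                               CharacterVector control_seqs, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_set<uint64_t> control;
  for (R_xlen_t i = 0; i < control_seqs.size(); ++i) {
    collect_canonical(as<std::string>(control_seqs[i]), k, control);
  }
  NumericVector res(sample_seqs.size());
  for (R_xlen_t i = 0; i < sample_seqs.size(); ++i) {
    std::unordered_set<uint64_t> km;
    collect_canonical(as<std::string>(sample_seqs[i]), k, km);
    if (km.empty()) { res[i] = NA_REAL; continue; }
    size_t hit = 0;
    for (uint64_t x : km) if (control.count(x)) ++hit;
    res[i] = (double)hit / (double)km.size();
  }
  return res;
}
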