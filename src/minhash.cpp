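#include <Rcpp.h>
#include <set>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// splitmix64 finalizer: well-mixed 64-bit hash of a 64-bit input
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Bottom-s MinHash sketch over canonical k-mers of a set of nucleotide
// strings. K-mers are 2-bit encoded (A=0,C=1,G=2,T=3) so numeric order
// equals lexicographic order and the canonical k-mer is min(fwd, revcomp).
// Windows containing non-ACGT characters are skipped. Hash values are
// returned right-shifted by 11 bits (53 bits, exactly representable as
// doubles), sorted ascending, distinct.
// [[Rcpp::export(name = ".minhash_bottom_sketch")]]
NumericVector minhash_bottom_sketch(CharacterVector seqs, int k, int s, double seed) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  if (s < 1) stop("sketch size s must be >= 1");
  const uint64_t useed = (uint64_t) seed;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::set<uint64_t> bottom; // ascending; at most s elements
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *p = CHAR(STRING_ELT(seqs, i));
    const size_t n = std::strlen(p);
    uint64_t fwd = 0, rc = 0;
    int run = 0; // length of current run of valid bases
    for (size_t j = 0; j < n; ++j) {
      int code;
      switch (p[j]) {
        case 'A': case 'a': code = 0; break;
        case 'C': case 'c': code = 1; break;
        case 'G': case 'g': code = 2; break;
        case 'T': case 't': code = 3; break;
        default: code = -1;
      }
      if (code < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) code) & mask;
      rc = (rc >> 2) | ((uint64_t) (3 - code) << (2 * (k - 1)));
      if (++run >= k) {
        const uint64_t canon = fwd < rc ? fwd : rc;
        const uint64_t h = splitmix64(canon ^ (useed * 0x9E3779B97F4A7C15ULL));
        if ((int) bottom.size() < s) {
          bottom.insert(h);
        } else if (h < *bottom.rbegin()) {
          if (bottom.insert(h).second) bottom.erase(std::prev(bottom.end()));
        }
      }
    }
  }
  NumericVector out(bottom.size());
  size_t idx = 0;
  for (uint64_t h : bottom) out[idx++] = (double) (h >> 11);
  return out;
}
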