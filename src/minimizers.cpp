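// Canonical (strand-symmetric) minimizer extraction for pooled-read
// deconvolution. k-mers are 2-bit encoded (k <= 26 so the code fits the 53
// exactly-representable bits of a double); the canonical form of a k-mer is
// min(code, revcomp code); a window of w consecutive k-mers contributes its
// smallest canonical code.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

// [[Rcpp::export]]
List cpp_minimizers(CharacterVector seqs, int k, int w) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  if (w < 1) stop("w must be >= 1");
  List out(seqs.size());
  const uint64_t msk = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string sq = as<std::string>(seqs[s]);
    int n = (int)sq.size();
    std::vector<uint64_t> canon;
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_code2(sq[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & msk;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run >= k) canon.push_back(std::min(fwd, rev));
    }
    std::vector<uint64_t> mins;
    int nk = (int)canon.size();
    if (nk >= w) {
      for (int i = 0; i + w <= nk; ++i) {
        uint64_t m = canon[i];
        for (int j = 1; j < w; ++j) m = std::min(m, canon[i + j]);
        mins.push_back(m);
      }
    } else if (nk > 0) {
      // short sequence: single window over whatever k-mers exist
      uint64_t m = canon[0];
      for (int j = 1; j < nk; ++j) m = std::min(m, canon[j]);
      mins.push_back(m);
    }
    std::sort(mins.begin(), mins.end());
    mins.erase(std::unique(mins.begin(), mins.end()), mins.end());
    NumericVector v(mins.size());
    for (size_t i = 0; i < mins.size(); ++i) v[i] = (double)mins[i];
    out[s] = v;
  }
  return out;
}
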