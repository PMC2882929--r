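// Perfect tandem-repeat (SSR) scan: maximal perfect runs of primitive motifs
// of 1-6 bp. Returns every maximal candidate run above the per-motif-length
// copy threshold; overlap resolution and motif canonicalization happen in R.
#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline bool acgt(char c) {
  char u = (c >= 'a' && c <= 'z') ? (char)(c - 32) : c;
  return u == 'A' || u == 'C' || u == 'G' || u == 'T';
}
static inline char up(char c) {
  return (c >= 'a' && c <= 'z') ? (char)(c - 32) : c;
}

static bool primitive(const std::string &motif) {
  int m = (int)motif.size();
  for (int p = 1; p < m; ++p) {
    if (m % p) continue;
    bool rep = true;
    for (int i = p; i < m && rep; ++i)
      if (motif[i] != motif[i - p]) rep = false;
    if (rep) return false;
  }
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_ssr_scan(std::string seq, NumericVector min_copies) {
  int n = (int)seq.size();
  std::vector<int> start, end, mlen;
  std::vector<double> copies;
  std::vector<std::string> motif;
  for (int m = 1; m <= 6 && m <= (int)min_copies.size(); ++m) {
    double minc = min_copies[m - 1];
    int i = 0;
    while (i + m <= n) {
      if (!acgt(seq[i])) { ++i; continue; }
      // extend run with period m starting at i
      int j = i;
      while (j + m < n && acgt(seq[j + m]) && up(seq[j + m]) == up(seq[j])) ++j;
      int run_len = (j + m) - i; // total bases in the maximal periodic run
      double cp = (double)run_len / (double)m;
      if (cp >= minc) {
        std::string mo = seq.substr(i, m);
        for (size_t z = 0; z < mo.size(); ++z) mo[z] = up(mo[z]);
        if (primitive(mo)) {
          start.push_back(i + 1);
          end.push_back(i + run_len);
          mlen.push_back(m);
          copies.push_back(cp);
          motif.push_back(mo);
        }
      }
      // next candidate run for this period starts after the mismatch position
      i = (run_len >= 2 * m) ? (j + 1) : (i + 1);
    }
  }
  return DataFrame::create(
    Named("start") = start, Named("end") = end,
    Named("motif") = motif, Named("motif_len") = mlen,
    Named("copy_number") = copies,
    Named("stringsAsFactors") = false);
}
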