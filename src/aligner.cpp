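// Seed-and-extend local aligner used for anchoring contigs/clones to a
// template genome, contig-vs-contig containment and repeat-library masking.
//
// Exact k-mer seeds (soft-masked bases excluded from seeding) are grouped
// into diagonal clusters; each cluster is rescored with a banded affine-gap
// local DP that tracks the alignment start, matched columns and alignment
// length without a traceback matrix. Gap cost convention: a gap of length L
// costs gap_open + L * gap_extend (same convention as Biostrings).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}
static inline bool soft_masked(char c) { return c >= 'a' && c <= 'z'; }

struct Seed { int q, t; };

struct Cluster {
  int qmin, qmax, tmin, tmax, dmin, dmax, last_q, last_d, n;
};

struct Hit {
  int qs, qe, ts, te;     // 1-based inclusive, on the oriented query
  double raw; int matches, len;
  char strand;
};

struct Cell { double sc; int qs, ts, m, len; };

static const double NEG = -1e18;

// banded affine local alignment over query window [q0,q1) (0-based) against
// template, diagonals restricted to [dlo, dhi] (d = t - q).
static bool band_align(const std::string &q, const std::string &t,
                       int q0, int q1, int dlo, int dhi,
                       double match, double mismatch,
                       double go, double ge, Hit &out) {
  const int W = dhi - dlo + 1;
  const int Tn = (int)t.size();
  std::vector<Cell> Mprev(W), Mcur(W), Xprev(W), Xcur(W), Yprev(W), Ycur(W);
  for (int j = 0; j < W; ++j) {
    Mprev[j].sc = NEG; Xprev[j].sc = NEG; Yprev[j].sc = NEG;
  }
  Cell best; best.sc = 0; best.qs = -1;
  int best_qe = -1, best_te = -1;
  double open_cost = go + ge;
  for (int qi = q0; qi < q1; ++qi) {
    int qc = base_code(q[qi]);
    for (int j = 0; j < W; ++j) {
      int ti = qi + dlo + j;
      Mcur[j].sc = NEG; Xcur[j].sc = NEG; Ycur[j].sc = NEG;
      if (ti < 0 || ti >= Tn) continue;
      int tc = base_code(t[ti]);
      double s = (qc >= 0 && qc == tc) ? match : mismatch;
      // M state: diagonal move; predecessor at (qi-1, ti-1) is same band col j
      double pm = Mprev[j].sc, px = Xprev[j].sc, py = Yprev[j].sc;
      double pbest = std::max(pm, std::max(px, py));
      Cell cur;
      if (pbest <= 0) { // fresh local start
        cur.sc = s; cur.qs = qi; cur.ts = ti; cur.m = (s == match); cur.len = 1;
      } else {
        const Cell &src = (pbest == pm) ? Mprev[j] : ((pbest == px) ? Xprev[j] : Yprev[j]);
        cur.sc = pbest + s; cur.qs = src.qs; cur.ts = src.ts;
        cur.m = src.m + (s == match); cur.len = src.len + 1;
      }
      if (cur.sc > 0) {
        Mcur[j] = cur;
        if (cur.sc > best.sc) { best = cur; best_qe = qi; best_te = ti; }
      }
      // X state: gap in query (consume template): from (qi, ti-1) = band col j-1, cur row
      if (j > 0) {
        double a = Mcur[j - 1].sc - open_cost;
        double b = Xcur[j - 1].sc - ge;
        if (a >= b && a > 0) {
          Xcur[j] = Mcur[j - 1]; Xcur[j].sc = a; Xcur[j].len += 1;
        } else if (b > a && b > 0) {
          Xcur[j] = Xcur[j - 1]; Xcur[j].sc = b; Xcur[j].len += 1;
        }
      }
      // Y state: gap in template (consume query): from (qi-1, ti) = band col j+1, prev row
      if (j + 1 < W) {
        double a = Mprev[j + 1].sc - open_cost;
        double b = Yprev[j + 1].sc - ge;
        if (a >= b && a > 0) {
          Ycur[j] = Mprev[j + 1]; Ycur[j].sc = a; Ycur[j].len += 1;
        } else if (b > a && b > 0) {
          Ycur[j] = Yprev[j + 1]; Ycur[j].sc = b; Ycur[j].len += 1;
        }
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  if (best.qs < 0 || best.sc <= 0) return false;
  out.qs = best.qs + 1; out.qe = best_qe + 1;
  out.ts = best.ts + 1; out.te = best_te + 1;
  out.raw = best.sc; out.matches = best.m; out.len = best.len;
  return true;
}

static void collect_kmers(const std::string &s, int k, bool mask,
                          std::vector<std::pair<uint32_t, int> > &out) {
  int n = (int)s.size();
  if (n < k) return;
  uint32_t code = 0, msk = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    bool bad = (b < 0) || (mask && soft_masked(s[i]));
    if (bad) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)b) & msk;
    if (++run >= k) out.push_back(std::make_pair(code, i - k + 1));
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break; case 'a': r[i] = 't'; break;
    case 'C': r[i] = 'G'; break; case 'c': r[i] = 'g'; break;
    case 'G': r[i] = 'C'; break; case 'g': r[i] = 'c'; break;
    case 'T': r[i] = 'A'; break; case 't': r[i] = 'a'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(CharacterVector query_seqs, CharacterVector query_ids,
                          CharacterVector template_seqs, CharacterVector template_ids,
                          int k, double match, double mismatch,
                          double gap_open, double gap_extend,
                          int max_occ, int max_seed_gap, int max_diag_drift,
                          int pad, int band_pad, bool mask_seeding) {
  std::vector<std::string> qid_out, tid_out;
  std::vector<int> qs_out, qe_out, ts_out, te_out;
  std::vector<double> raw_out, ident_out;
  std::vector<std::string> strand_out;

  for (int tix = 0; tix < template_seqs.size(); ++tix) {
    std::string tseq = as<std::string>(template_seqs[tix]);
    std::string tid = as<std::string>(template_ids[tix]);
    std::vector<std::pair<uint32_t, int> > tk;
    collect_kmers(tseq, k, mask_seeding, tk);
    std::unordered_map<uint32_t, std::vector<int> > index;
    index.reserve(tk.size() * 2 + 16);
    for (size_t i = 0; i < tk.size(); ++i) index[tk[i].first].push_back(tk[i].second);

    for (int qix = 0; qix < query_seqs.size(); ++qix) {
      std::string qfwd = as<std::string>(query_seqs[qix]);
      std::string qid = as<std::string>(query_ids[qix]);
      int Lq = (int)qfwd.size();
      if (Lq < k) continue;
      for (int sdx = 0; sdx < 2; ++sdx) {
        char strand = (sdx == 0) ? '+' : '-';
        std::string qseq = (sdx == 0) ? qfwd : revcomp(qfwd);
        std::vector<std::pair<uint32_t, int> > qk;
        collect_kmers(qseq, k, mask_seeding, qk);
        std::vector<Seed> seeds;
        for (size_t i = 0; i < qk.size(); ++i) {
          std::unordered_map<uint32_t, std::vector<int> >::iterator it =
            index.find(qk[i].first);
          if (it == index.end()) continue;
          if ((int)it->second.size() > max_occ) continue;
          for (size_t j = 0; j < it->second.size(); ++j) {
            Seed sd; sd.q = qk[i].second; sd.t = it->second[j];
            seeds.push_back(sd);
          }
        }
        if (seeds.empty()) continue;
        std::sort(seeds.begin(), seeds.end(),
                  [](const Seed &a, const Seed &b) {
                    return a.q < b.q || (a.q == b.q && a.t < b.t);
                  });
        std::vector<Cluster> clusters;
        std::vector<int> active; // indices into clusters
        for (size_t i = 0; i < seeds.size(); ++i) {
          int d = seeds[i].t - seeds[i].q;
          int bestc = -1, bestdd = max_diag_drift + 1;
          for (size_t a = 0; a < active.size();) {
            Cluster &cl = clusters[active[a]];
            if (seeds[i].q - cl.last_q > max_seed_gap) {
              active[a] = active.back(); active.pop_back(); continue;
            }
            int dd = std::abs(d - cl.last_d);
            if (dd <= max_diag_drift && dd < bestdd) { bestdd = dd; bestc = active[a]; }
            ++a;
          }
          if (bestc < 0) {
            Cluster cl; cl.qmin = cl.qmax = seeds[i].q; cl.tmin = cl.tmax = seeds[i].t;
            cl.dmin = cl.dmax = d; cl.last_q = seeds[i].q; cl.last_d = d; cl.n = 1;
            clusters.push_back(cl);
            active.push_back((int)clusters.size() - 1);
          } else {
            Cluster &cl = clusters[bestc];
            cl.qmax = std::max(cl.qmax, seeds[i].q);
            cl.tmin = std::min(cl.tmin, seeds[i].t);
            cl.tmax = std::max(cl.tmax, seeds[i].t);
            cl.dmin = std::min(cl.dmin, d);
            cl.dmax = std::max(cl.dmax, d);
            cl.last_q = seeds[i].q; cl.last_d = d; cl.n += 1;
          }
        }
        for (size_t c = 0; c < clusters.size(); ++c) {
          Cluster &cl = clusters[c];
          int q0 = std::max(0, cl.qmin - pad);
          int q1 = std::min(Lq, cl.qmax + k + pad);
          int dlo = cl.dmin - band_pad, dhi = cl.dmax + band_pad;
          Hit h;
          if (!band_align(qseq, tseq, q0, q1, dlo, dhi,
                          match, mismatch, gap_open, gap_extend, h)) continue;
          h.strand = strand;
          int aqs = h.qs, aqe = h.qe;
          if (strand == '-') { aqs = Lq - h.qe + 1; aqe = Lq - h.qs + 1; }
          qid_out.push_back(qid); tid_out.push_back(tid);
          qs_out.push_back(aqs); qe_out.push_back(aqe);
          ts_out.push_back(h.ts); te_out.push_back(h.te);
          raw_out.push_back(h.raw);
          ident_out.push_back((double)h.matches / (double)h.len);
          strand_out.push_back(std::string(1, strand));
        }
      }
    }
  }
  return DataFrame::create(
    Named("query_id") = qid_out, Named("query_start") = qs_out,
    Named("query_end") = qe_out, Named("template_id") = tid_out,
    Named("template_start") = ts_out, Named("template_end") = te_out,
    Named("strand") = strand_out, Named("raw_score") = raw_out,
    Named("identity") = ident_out,
    Named("stringsAsFactors") = false);
}
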