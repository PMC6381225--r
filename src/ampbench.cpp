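#include <Rcpp.h>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// base -> index; A=0 C=1 G=2 T=3, anything else -1
static inline int base_idx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

// Banded Levenshtein distance with cutoff: returns min(d(a,b), kmax + 1).
static int bounded_lev(const char *a, int la, const char *b, int lb, int kmax) {
  if (std::abs(la - lb) > kmax) return kmax + 1;
  if (la == 0) return lb <= kmax ? lb : kmax + 1;
  if (lb == 0) return la <= kmax ? la : kmax + 1;
  const int INF = kmax + 1;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j <= kmax ? j : INF;
  for (int i = 1; i <= la; ++i) {
    int lo = std::max(1, i - kmax), hi = std::min(lb, i + kmax);
    cur[lo - 1] = (i - kmax <= 1) ? std::min(i, INF) : INF;
    int rowmin = cur[lo - 1];
    for (int j = lo; j <= hi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = (j <= i + kmax - 1) ? prev[j] + 1 : INF;
      int ins = (j - 1 >= lo - 1) ? cur[j - 1] + 1 : INF;
      int v = std::min(sub, std::min(del, ins));
      cur[j] = std::min(v, INF);
      rowmin = std::min(rowmin, cur[j]);
    }
    if (hi < lb) cur[hi + 1 > lb ? lb : hi + 1] = INF;
    if (rowmin > kmax) return kmax + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[lb], INF);
}

// [[Rcpp::export(name = ".bounded_levenshtein")]]
IntegerVector bounded_levenshtein_cpp(CharacterVector a, CharacterVector b, int kmax) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *sa = CHAR(STRING_ELT(a, i));
    const char *sb = CHAR(STRING_ELT(b, i));
    out[i] = bounded_lev(sa, std::strlen(sa), sb, std::strlen(sb), kmax);
  }
  return out;
}

// All-pairs bounded Levenshtein: rows = x, cols = y; entries capped at kmax + 1.
// [[Rcpp::export(name = ".dist_bounded_matrix")]]
IntegerMatrix dist_bounded_matrix_cpp(CharacterVector x, CharacterVector y, int kmax) {
  int n = x.size(), m = y.size();
  IntegerMatrix out(n, m);
  std::vector<const char *> xs(n), ys(m);
  std::vector<int> xl(n), yl(m);
  for (int i = 0; i < n; ++i) { xs[i] = CHAR(STRING_ELT(x, i)); xl[i] = std::strlen(xs[i]); }
  for (int j = 0; j < m; ++j) { ys[j] = CHAR(STRING_ELT(y, j)); yl[j] = std::strlen(ys[j]); }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = bounded_lev(xs[i], xl[i], ys[j], yl[j], kmax);
  return out;
}

// Hamming distance with early exit; strings must be equal length (error otherwise).
// [[Rcpp::export(name = ".hamming_bounded_matrix")]]
IntegerMatrix hamming_bounded_matrix_cpp(CharacterVector x, CharacterVector y, int kmax) {
  int n = x.size(), m = y.size();
  IntegerMatrix out(n, m);
  std::vector<const char *> xs(n), ys(m);
  std::vector<int> xl(n), yl(m);
  for (int i = 0; i < n; ++i) { xs[i] = CHAR(STRING_ELT(x, i)); xl[i] = std::strlen(xs[i]); }
  for (int j = 0; j < m; ++j) { ys[j] = CHAR(STRING_ELT(y, j)); yl[j] = std::strlen(ys[j]); }
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (xl[i] != yl[j]) stop("hamming distance requires equal-length sequences");
      int mm = 0;
      for (int p = 0; p < xl[i]; ++p) {
        if (xs[i][p] != ys[j][p] && ++mm > kmax) break;
      }
      out(i, j) = mm > kmax ? kmax + 1 : mm;
    }
  }
  return out;
}

static inline double phred_err(int q) { return std::pow(10.0, -q / 10.0); }

// Merge read pairs by best ungapped overlap (maximal matches among overlaps
// with <= maxdiffs mismatches). Qualities are phred+33 strings. Returns
// merged sequence/quality, status (1 merged, 0 no admissible overlap),
// overlap length and mismatch count. Posterior qualities: agreement ->
// e1*e2, disagreement -> e_hi/(e_hi+e_lo) keeping the higher-quality base;
// clamped to [2, 41].
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector fwd, CharacterVector rev,
                     CharacterVector fwd_q, CharacterVector rev_q,
                     int maxdiffs, int min_overlap) {
  int n = fwd.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector status(n), overlap(n), ndiff(n);
  std::string rc, rcq, seq, qual;
  for (int i = 0; i < n; ++i) {
    const char *f = CHAR(STRING_ELT(fwd, i));
    const char *r = CHAR(STRING_ELT(rev, i));
    const char *fq = CHAR(STRING_ELT(fwd_q, i));
    const char *rq = CHAR(STRING_ELT(rev_q, i));
    int Lf = std::strlen(f), Lr = std::strlen(r);
    rc.assign(Lr, 'N'); rcq.assign(Lr, '!');
    for (int p = 0; p < Lr; ++p) {
      rc[p] = comp_base(r[Lr - 1 - p]);
      rcq[p] = rq[Lr - 1 - p];
    }
    int best_score = -1, best_o = 0, best_mm = 0;
    int omax = std::min(Lf, Lr);
    for (int o = min_overlap; o <= omax; ++o) {
      int mm = 0;
      const char *ft = f + (Lf - o);
      for (int p = 0; p < o; ++p) {
        if (ft[p] != rc[p] && ++mm > maxdiffs) break;
      }
      if (mm <= maxdiffs) {
        int score = o - mm;
        if (score > best_score || (score == best_score && o > best_o)) {
          best_score = score; best_o = o; best_mm = mm;
        }
      }
    }
    if (best_score < 0) {
      status[i] = 0; mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      overlap[i] = 0; ndiff[i] = 0;
      continue;
    }
    int o = best_o, L = Lf + Lr - o;
    seq.assign(L, 'N'); qual.assign(L, '!');
    for (int p = 0; p < Lf - o; ++p) { seq[p] = f[p]; qual[p] = fq[p]; }
    for (int p = 0; p < o; ++p) {
      char bf = f[Lf - o + p], br = rc[p];
      int qf = fq[Lf - o + p] - 33, qr = rcq[p] - 33;
      double ef = phred_err(qf), er = phred_err(qr);
      char base; double epost;
      if (bf == br) {
        base = bf; epost = ef * er;
      } else if (qf >= qr) {
        base = bf; epost = ef / (ef + er);
      } else {
        base = br; epost = er / (er + ef);
      }
      int q = (int) std::lround(-10.0 * std::log10(std::max(epost, 1e-12)));
      if (q > 41) q = 41;
      if (q < 2) q = 2;
      seq[Lf - o + p] = base; qual[Lf - o + p] = (char)(q + 33);
    }
    for (int p = o; p < Lr; ++p) { seq[Lf + p - o] = rc[p]; qual[Lf + p - o] = rcq[p]; }
    status[i] = 1; mseq[i] = seq; mqual[i] = qual;
    overlap[i] = o; ndiff[i] = best_mm;
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["status"] = status, _["overlap"] = overlap,
                      _["diffs"] = ndiff);
}

// Expected errors per quality string: sum of 10^(-q/10).
// [[Rcpp::export(name = ".phred_expected_errors")]]
NumericVector phred_expected_errors_cpp(CharacterVector qual) {
  int n = qual.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(qual, i));
    double ee = 0.0;
    for (int p = 0; q[p]; ++p) ee += phred_err(q[p] - 33);
    out[i] = ee;
  }
  return out;
}

// Log-likelihood of reading each sequence from each centroid under a 4x4
// (from, to) log-probability matrix; equal-length sequences only.
// [[Rcpp::export(name = ".loglambda_matrix")]]
NumericMatrix loglambda_matrix_cpp(CharacterVector seqs, CharacterVector centroids,
                                   NumericMatrix log_m) {
  int n = seqs.size(), m = centroids.size();
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = std::strlen(s);
    for (int j = 0; j < m; ++j) {
      const char *c = CHAR(STRING_ELT(centroids, j));
      if ((int) std::strlen(c) != L) stop("sequences must be equal length");
      double ll = 0.0;
      for (int p = 0; p < L; ++p) {
        int fi = base_idx(c[p]), ti = base_idx(s[p]);
        if (fi < 0 || ti < 0) { fi = 0; ti = 3; } // unknown base: worst case
        ll += log_m(fi, ti);
      }
      out(i, j) = ll;
    }
  }
  return out;
}

// Weighted (from, to) base transition counts of each sequence against the
// centroid of its assigned cluster.
// [[Rcpp::export(name = ".transition_counts")]]
NumericMatrix transition_counts_cpp(CharacterVector seqs, CharacterVector centroids,
                                    IntegerVector assign, NumericVector weight) {
  int n = seqs.size();
  NumericMatrix out(4, 4);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    const char *c = CHAR(STRING_ELT(centroids, assign[i] - 1));
    double w = weight[i];
    for (int p = 0; s[p] && c[p]; ++p) {
      int fi = base_idx(c[p]), ti = base_idx(s[p]);
      if (fi >= 0 && ti >= 0) out(fi, ti) += w;
    }
  }
  return out;
}

// Longest common prefix / suffix lengths of a candidate against each parent.
// [[Rcpp::export(name = ".lcp_lcs")]]
List lcp_lcs_cpp(std::string candidate, CharacterVector parents) {
  int m = parents.size(), L = candidate.size();
  IntegerVector lcp(m), lcs(m);
  for (int j = 0; j < m; ++j) {
    const char *p = CHAR(STRING_ELT(parents, j));
    int Lp = std::strlen(p);
    int a = 0, mn = std::min(L, Lp);
    while (a < mn && candidate[a] == p[a]) ++a;
    int b = 0;
    while (b < mn && candidate[L - 1 - b] == p[Lp - 1 - b]) ++b;
    lcp[j] = a; lcs[j] = b;
  }
  return List::create(_["lcp"] = lcp, _["lcs"] = lcs);
}
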