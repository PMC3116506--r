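#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Gotoh affine-gap alignment, global on the read, free reference 3' overhang
// (reads are quality-trimmed prefixes of the template, so the uncovered
// reference tail carries no penalty). Gap cost = open + extend * length,
// extension charged for every gap base. States: M diagonal, X gap in read
// (deletion), Y gap in reference (insertion). Deterministic tie-breaking
// prefers M over X over Y; among equal end columns the largest reference
// extent is kept.

static const double NEG = -1e15;

// [[Rcpp::export]]
List cpp_align_affine(std::string read, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  const double go = gap_open + gap_extend;

  std::vector<double> M((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> X((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> Y((size_t)(n + 1) * (m + 1), NEG);
  const size_t W = (size_t) m + 1;
#define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

  M[IDX(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) X[IDX(0, j)] = -(gap_open + gap_extend * j);
  for (int i = 1; i <= n; ++i) Y[IDX(i, 0)] = -(gap_open + gap_extend * i);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (read[i - 1] == ref[j - 1]) ? match : -mismatch;
      double d = M[IDX(i - 1, j - 1)];
      if (X[IDX(i - 1, j - 1)] > d) d = X[IDX(i - 1, j - 1)];
      if (Y[IDX(i - 1, j - 1)] > d) d = Y[IDX(i - 1, j - 1)];
      M[IDX(i, j)] = d + s;

      double bx = M[IDX(i, j - 1)] - go;
      if (X[IDX(i, j - 1)] - gap_extend > bx) bx = X[IDX(i, j - 1)] - gap_extend;
      if (Y[IDX(i, j - 1)] - go > bx) bx = Y[IDX(i, j - 1)] - go;
      X[IDX(i, j)] = bx;

      double by = M[IDX(i - 1, j)] - go;
      if (Y[IDX(i - 1, j)] - gap_extend > by) by = Y[IDX(i - 1, j)] - gap_extend;
      if (X[IDX(i - 1, j)] - go > by) by = X[IDX(i - 1, j)] - go;
      Y[IDX(i, j)] = by;
    }
  }

  // end: read consumed, any reference extent j, remaining tail free
  double best = NEG * 2;
  int bj = 0, bs = 0; // 0 = M, 1 = X, 2 = Y
  for (int j = 0; j <= m; ++j) {
    double v[3] = { M[IDX(n, j)], X[IDX(n, j)], Y[IDX(n, j)] };
    int s = 0;
    if (v[1] > v[0]) s = 1;
    if (v[2] > v[s]) s = 2;
    if (v[s] >= best) { best = v[s]; bj = j; bs = s; }
  }

  // traceback
  std::string ar, aq; // aligned ref / aligned read, reversed
  int i = n, j = bj, st = bs;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (st == 0) {
      const double s = (read[i - 1] == ref[j - 1]) ? match : -mismatch;
      ar.push_back(ref[j - 1]);
      aq.push_back(read[i - 1]);
      // prefer gap-state predecessors so that tied gaps land as far 3'
      // (right) as possible: reading the alignment 5'->3' this realizes
      // the match/mismatch > deletion > insertion preference
      const double want = M[IDX(i, j)] - s;
      int prev;
      if (std::abs(Y[IDX(i - 1, j - 1)] - want) < eps) prev = 2;
      else if (std::abs(X[IDX(i - 1, j - 1)] - want) < eps) prev = 1;
      else prev = 0;
      --i; --j; st = prev;
    } else if (st == 1) { // gap in read, consumes ref j
      ar.push_back(ref[j - 1]);
      aq.push_back('-');
      const double want = X[IDX(i, j)];
      int prev;
      if (std::abs(Y[IDX(i, j - 1)] - go - want) < eps) prev = 2;
      else if (std::abs(X[IDX(i, j - 1)] - gap_extend - want) < eps) prev = 1;
      else prev = 0;
      --j; st = prev;
    } else { // gap in ref, consumes read i
      ar.push_back('-');
      aq.push_back(read[i - 1]);
      const double want = Y[IDX(i, j)];
      int prev;
      if (std::abs(Y[IDX(i - 1, j)] - gap_extend - want) < eps) prev = 2;
      else if (std::abs(X[IDX(i - 1, j)] - go - want) < eps) prev = 1;
      else prev = 0;
      --i; st = prev;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && st != 1) st = 1; // only read-gap columns can remain
    if (j == 0 && st != 2) st = 2;
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(aq.begin(), aq.end());
#undef IDX

  return List::create(_["score"] = best,
                      _["aligned_ref"] = ar,
                      _["aligned_read"] = aq,
                      _["ref_end"] = bj);
}
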