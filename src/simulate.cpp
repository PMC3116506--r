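#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

// Per-read error injection. A is an L x 4 matrix of per-position logits
// (intercept + position + homopolymer terms) for the four event types in the
// order insertion, deletion, mismatch, ambiguous; B is an n_reads x 4 matrix
// of per-read offsets (y-gradient + region offset). Each covered reference
// position draws at most one event from a single categorical draw; the sum of
// the four per-type probabilities must not exceed 1 (no clipping). tlen gives
// the covered reference length of each read. All randomness comes from R's
// RNG, so set.seed() upstream makes the output reproducible.

static inline double inv_logit(double x) {
  if (x < -700.0) return 0.0;
  if (x > 700.0) return 1.0;
  return 1.0 / (1.0 + std::exp(-x));
}

static inline int rand_int(int k) { // uniform on 0..k-1
  int v = (int) std::floor(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// [[Rcpp::export]]
List cpp_inject_errors(std::string ref, NumericMatrix A, NumericMatrix B,
                       IntegerVector tlen) {
  const int L = (int) ref.size();
  if (A.nrow() != L || A.ncol() != 4)
    stop("logit matrix A must be reference-length x 4");
  const int n = tlen.size();
  if (B.nrow() != n || B.ncol() != 4)
    stop("offset matrix B must be n_reads x 4");
  static const char BASES[] = "ACGT";

  CharacterVector seqs(n);
  std::vector<int> ev_read, ev_pos, ev_type;
  std::string out;
  out.reserve(L + 16);

  for (int r = 0; r < n; ++r) {
    const int T = tlen[r];
    if (T < 1 || T > L) stop("covered length outside 1..reference length");
    out.clear();
    for (int p = 0; p < T; ++p) {
      double pr[4], tot = 0.0;
      for (int t = 0; t < 4; ++t) {
        pr[t] = inv_logit(A(p, t) + B(r, t));
        tot += pr[t];
      }
      if (tot > 1.0)
        stop("per-position event probabilities sum to %.4f > 1 at position %d; "
             "adjust the coefficient vector (clipping is not allowed)", tot, p + 1);
      const double u = unif_rand();
      int ev = -1;
      double c = 0.0;
      for (int t = 0; t < 4; ++t) {
        c += pr[t];
        if (u < c) { ev = t; break; }
      }
      const char base = ref[p];
      if (ev < 0) {
        out.push_back(base);
        continue;
      }
      ev_read.push_back(r + 1);
      ev_pos.push_back(p + 1);
      ev_type.push_back(ev + 1);
      switch (ev) {
      case 0: // insertion: random base after this position
        out.push_back(base);
        out.push_back(BASES[rand_int(4)]);
        break;
      case 1: // deletion
        break;
      case 2: { // mismatch: substitute a different base
        int k = rand_int(3);
        char sub = BASES[k];
        if (sub == base) sub = BASES[3];
        out.push_back(sub);
        break;
      }
      case 3: // ambiguous call
        out.push_back('N');
        break;
      }
    }
    seqs[r] = out;
  }

  return List::create(_["sequences"] = seqs,
                      _["ev_read"] = wrap(ev_read),
                      _["ev_pos"] = wrap(ev_pos),
                      _["ev_type"] = wrap(ev_type));
}
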