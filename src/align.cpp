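#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) of a read against a reference.
// A gap of length L scores gap_open + L * gap_extend. Traceback ties are
// broken deletion > insertion > diagonal (and a gap is extended rather
// than closed when both are optimal); gap runs are then left-shifted
// while the flanking bases permit, so indel placement is deterministic
// and left-aligned.
//
// Op letters over alignment columns: M = read/ref pair (match or
// mismatch), D = ref base deleted from the read, I = read base inserted
// relative to the ref.

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static inline bool eq(double a, double b) { return std::abs(a - b) < 1e-6; }

// [[Rcpp::export]]
List cpp_align_global(std::string read, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = read.size();   // rows: read
  const int m = ref.size();    // cols: ref
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, NEG_INF), E((n + 1) * W, NEG_INF),
      F((n + 1) * W, NEG_INF);
  H[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    E[j] = gap_open + j * gap_extend;
    H[j] = E[j];
  }
  for (int i = 1; i <= n; ++i) {
    F[i * W] = gap_open + i * gap_extend;
    H[i * W] = F[i * W];
  }
  for (int i = 1; i <= n; ++i) {
    const char rb = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      double e1 = H[ij - 1] + gap_open + gap_extend;
      double e2 = E[ij - 1] + gap_extend;
      E[ij] = e1 > e2 ? e1 : e2;
      double f1 = H[ij - W] + gap_open + gap_extend;
      double f2 = F[ij - W] + gap_extend;
      F[ij] = f1 > f2 ? f1 : f2;
      double d = H[ij - W - 1] + ((rb == ref[j - 1]) ? match : mismatch);
      double best = E[ij];
      if (F[ij] > best) best = F[ij];
      if (d > best) best = d;
      H[ij] = best;
    }
  }

  // traceback (built right-to-left, reversed at the end)
  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m, state = 0;  // 0 = H, 1 = E (deletion), 2 = F (insertion)
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    if (state == 0) {
      if (j > 0 && eq(H[ij], E[ij])) state = 1;
      else if (i > 0 && eq(H[ij], F[ij])) state = 2;
      else { ops.push_back('M'); --i; --j; continue; }
    }
    if (state == 1) {
      ops.push_back('D');
      if (!eq(E[ij], E[ij - 1] + gap_extend)) state = 0;
      --j;
    } else {
      ops.push_back('I');
      if (!eq(F[ij], F[ij - W] + gap_extend)) state = 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // left-align gap runs: a run shifts one column left when the preceding
  // column is an M and the base entering the run equals the base leaving
  // it (score and match status are preserved).
  bool moved = true;
  while (moved) {
    moved = false;
    const size_t L = ops.size();
    std::vector<int> ri(L), rj(L);  // read/ref index consumed at column c
    int a = 0, b = 0;
    for (size_t c = 0; c < L; ++c) {
      ri[c] = a; rj[c] = b;
      if (ops[c] == 'M') { ++a; ++b; }
      else if (ops[c] == 'D') { ++b; }
      else { ++a; }
    }
    for (size_t c = 0; c < L; ++c) {
      if (ops[c] == 'M') continue;
      size_t e = c;
      while (e < L && ops[e] == ops[c]) ++e;
      if (c > 0 && ops[c - 1] == 'M') {
        bool ok = (ops[c] == 'D')
          ? (ref[rj[c] - 1] == ref[rj[e - 1]])
          : (read[ri[c] - 1] == read[ri[e - 1]]);
        if (ok) { std::swap(ops[c - 1], ops[e - 1]); moved = true; }
      }
      c = e - 1;
    }
  }

  return List::create(_["score"] = H[n * W + m], _["ops"] = ops);
}
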