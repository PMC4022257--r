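#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Free-end-gap (overlap) Needleman-Wunsch. Scores: match +1, mismatch -1,
// gap -2; leading/trailing gaps on either sequence are free. Identity is
// matches / alignment columns, where columns include the unaligned terminal
// flanks, so disjoint sequences score 0 rather than NaN.
static double nw_identity_one(const std::string &a, const std::string &b,
                              double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("identity(): sequences must be nonempty");
  std::vector<double> prev(m + 1), cur(m + 1);
  // traceback: 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) prev[j] = 0.0;  // free leading gaps
  for (int j = 1; j <= m; ++j) tb[j] = 2;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double best = sdiag;
      unsigned char dir = 0;
      if (sup > best) { best = sup; dir = 1; }
      if (sleft > best) { best = sleft; dir = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
      // keep full DP matrix scores only via traceback; scores row-rolled
    }
    std::swap(prev, cur);
  }
  // prev now holds row n. Best end cell: max over last row and last column.
  // Last column scores were overwritten by rolling; recompute by a second
  // pass storing column m scores.
  // Simpler: rerun DP keeping column m and final row.
  std::vector<double> colm(n + 1), rowc(m + 1);
  {
    std::vector<double> p2(m + 1), c2(m + 1);
    for (int j = 0; j <= m; ++j) p2[j] = 0.0;
    colm[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
      c2[0] = 0.0;
      for (int j = 1; j <= m; ++j) {
        double sdiag = p2[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
        double sup = p2[j] + gap;
        double sleft = c2[j - 1] + gap;
        double best = sdiag;
        if (sup > best) best = sup;
        if (sleft > best) best = sleft;
        c2[j] = best;
      }
      colm[i] = c2[m];
      std::swap(p2, c2);
    }
    for (int j = 0; j <= m; ++j) rowc[j] = p2[j];
  }
  int bi = n, bj = m;
  double best = rowc[m];
  for (int j = m - 1; j >= 0; --j)
    if (rowc[j] > best) { best = rowc[j]; bi = n; bj = j; }
  for (int i = n - 1; i >= 0; --i)
    if (colm[i] > best) { best = colm[i]; bi = i; bj = m; }
  // trailing flanks (unaligned overhang on one sequence)
  long matches = 0, cols = (n - bi) + (m - bj);
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j; ++cols;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      --i; ++cols;
    } else {
      --j; ++cols;
    }
  }
  if (cols == 0) return 0.0;
  return (double)matches / (double)cols;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_identity")]]
NumericVector cpp_identity(CharacterVector a, CharacterVector b,
                           double match = 1.0, double mismatch = -1.0,
                           double gap = -2.0) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("identity(): lengths must match or be 1");
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : k]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : k]);
    out[k] = nw_identity_one(sa, sb, match, mismatch, gap);
  }
  return out;
}

// Max identity of one query against a set of references; early exit once the
// stop threshold is reached (used by the greedy clusterer against a cluster's
// neighbor-seed set).
// [[Rcpp::export(name = ".cpp_identity_max")]]
double cpp_identity_max(std::string query, CharacterVector refs,
                        double stop_at = 2.0, double match = 1.0,
                        double mismatch = -1.0, double gap = -2.0) {
  double best = 0.0;
  for (R_xlen_t k = 0; k < refs.size(); ++k) {
    double id = nw_identity_one(query, as<std::string>(refs[k]),
                                match, mismatch, gap);
    if (id > best) best = id;
    if (best >= stop_at) break;
  }
  return best;
}
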