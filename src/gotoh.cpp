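#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Three-state affine-gap global alignment (Gotoh) over a precomputed
// column-score matrix. cost(i,j) is the score of aligning unit i of the
// first profile/sequence against unit j of the second. A gap run of length
// R costs gop + (R-1)*gep. States: M (match column), GA (gap in the first
// input, second advances), GB (gap in the second input, first advances).
// Ties prefer M, then GA, then GB, so output is deterministic.

static const int ST_M = 0, ST_GA = 1, ST_GB = 2;

// gop_a/gep_a: penalties for a gap run placed in the first input (second
// advances); gop_b/gep_b: for a gap run in the second. Pairwise alignment
// uses equal penalties; profile merges scale each side by its row count so
// the DP optimises the same sum-of-pairs objective the result is scored by.
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix cost, double gop_a, double gep_a,
                 double gop_b, double gep_b) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n < 1 || m < 1) stop("empty input to gotoh_align");
  const double NEG = -std::numeric_limits<double>::infinity();

  // DP tables, (n+1) x (m+1)
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> GA((n + 1) * (m + 1), NEG); // gap in first, consume j
  std::vector<double> GB((n + 1) * (m + 1), NEG); // gap in second, consume i
  // traceback: predecessor state for each cell/state
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pGA((n + 1) * (m + 1), -1);
  std::vector<signed char> pGB((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    GA[at(0, j)] = -gop_a - (j - 1) * gep_a;
    pGA[at(0, j)] = (j == 1) ? ST_M : ST_GA;
  }
  for (int i = 1; i <= n; ++i) {
    GB[at(i, 0)] = -gop_b - (i - 1) * gep_b;
    pGB[at(i, 0)] = (i == 1) ? ST_M : ST_GB;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: ties prefer predecessor M > GA > GB
      {
        double bm = M[at(i - 1, j - 1)], bga = GA[at(i - 1, j - 1)],
               bgb = GB[at(i - 1, j - 1)];
        double best = bm; signed char ps = ST_M;
        if (bga > best) { best = bga; ps = ST_GA; }
        if (bgb > best) { best = bgb; ps = ST_GB; }
        if (best > NEG) {
          M[at(i, j)] = best + cost(i - 1, j - 1);
          pM[at(i, j)] = ps;
        }
      }
      // GA: consume j, gap char in first input
      {
        double open_m = M[at(i, j - 1)] - gop_a;
        double ext = GA[at(i, j - 1)] - gep_a;
        double open_gb = GB[at(i, j - 1)] - gop_a;
        double best = open_m; signed char ps = ST_M;
        if (ext > best) { best = ext; ps = ST_GA; }
        if (open_gb > best) { best = open_gb; ps = ST_GB; }
        if (best > NEG) { GA[at(i, j)] = best; pGA[at(i, j)] = ps; }
      }
      // GB: consume i, gap char in second input
      {
        double open_m = M[at(i - 1, j)] - gop_b;
        double open_ga = GA[at(i - 1, j)] - gop_b;
        double ext = GB[at(i - 1, j)] - gep_b;
        double best = open_m; signed char ps = ST_M;
        if (open_ga > best) { best = open_ga; ps = ST_GA; }
        if (ext > best) { best = ext; ps = ST_GB; }
        if (best > NEG) { GB[at(i, j)] = best; pGB[at(i, j)] = ps; }
      }
    }
  }

  double best = M[at(n, m)]; int st = ST_M;
  if (GA[at(n, m)] > best) { best = GA[at(n, m)]; st = ST_GA; }
  if (GB[at(n, m)] > best) { best = GB[at(n, m)]; st = ST_GB; }

  // traceback
  std::vector<int> ai, bj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (st == ST_M) {
      prev = pM[at(i, j)];
      ai.push_back(i); bj.push_back(j);
      --i; --j;
    } else if (st == ST_GA) {
      prev = pGA[at(i, j)];
      ai.push_back(0); bj.push_back(j);
      --j;
    } else {
      prev = pGB[at(i, j)];
      ai.push_back(i); bj.push_back(0);
      --i;
    }
    st = prev;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());

  return List::create(_["score"] = best,
                      _["a"] = IntegerVector(ai.begin(), ai.end()),
                      _["b"] = IntegerVector(bj.begin(), bj.end()));
}
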