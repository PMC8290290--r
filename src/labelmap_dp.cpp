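#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming alignment of two ordered label-site lists.
//
// A matching is an increasing chain of site pairs.  Each matched site pair
// earns `site_bonus`; each transition between consecutive matched pairs
// pays `sizing_penalty * rel_err / tol` (rel_err = |dq - dr| / max(dq, dr)
// of the inter-site spacings, transitions with rel_err > tol are
// disallowed) plus `skip_penalty` per skipped site on either side.  Up to
// `max_skip` consecutive skips per side are considered.  Terminal
// unmatched sites are free (local semantics).  Returns the best chain.
//
// [[Rcpp::export(name = ".labelmap_dp")]]
List labelmap_dp(NumericVector q, NumericVector r, double tol,
                 double site_bonus, double skip_penalty,
                 double sizing_penalty, int max_skip) {
  int n = q.size(), m = r.size();
  NumericMatrix S(n, m);
  IntegerMatrix bi(n, m), bj(n, m);
  double best = R_NegInf;
  int besti = -1, bestj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double sc = site_bonus;  // start a new chain here
      bi(i, j) = -1; bj(i, j) = -1;
      for (int pi = i - 1; pi >= 0 && pi >= i - 1 - max_skip; --pi) {
        for (int pj = j - 1; pj >= 0 && pj >= j - 1 - max_skip; --pj) {
          double dq = q[i] - q[pi];
          double dr = r[j] - r[pj];
          double mx = dq > dr ? dq : dr;
          if (mx <= 0) continue;
          double rel = std::abs(dq - dr) / mx;
          if (rel > tol) continue;
          double cand = S(pi, pj) + site_bonus
            - sizing_penalty * rel / tol
            - skip_penalty * ((i - pi - 1) + (j - pj - 1));
          if (cand > sc) {
            sc = cand;
            bi(i, j) = pi; bj(i, j) = pj;
          }
        }
      }
      S(i, j) = sc;
      if (sc > best) { best = sc; besti = i; bestj = j; }
    }
  }
  std::vector<int> qi, ri;
  int ci = besti, cj = bestj;
  while (ci >= 0 && cj >= 0) {
    qi.push_back(ci + 1);  // 1-based for R
    ri.push_back(cj + 1);
    int ni = bi(ci, cj), nj = bj(ci, cj);
    ci = ni; cj = nj;
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(ri.begin(), ri.end());
  return List::create(_["score"] = best,
                      _["q_idx"] = wrap(qi),
                      _["r_idx"] = wrap(ri));
}
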