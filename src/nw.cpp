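#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback preference on ties: diagonal, then up (gap in b), then left
// (gap in a), giving a deterministic alignment.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b,
              double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // 0 = diag, 1 = up, 2 = left
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double best = d; unsigned char dir = 0;
      if (u > best) { best = u; dir = 1; }
      if (l > best) { best = l; dir = 2; }
      cur[j] = best;
      tb[i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  double score = prev[m];
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score,
                      _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}

// Pairwise difference scores over an alignment: proportion of columns at
// which the two rows differ, among columns where not both are gaps.
// [[Rcpp::export(name = ".diff_scores")]]
NumericMatrix diff_scores(CharacterVector rows) {
  const int n = rows.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(rows[i]);
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      long diff = 0, eligible = 0;
      const std::string &x = s[i], &y = s[j];
      for (size_t k = 0; k < x.size(); ++k) {
        if (x[k] == '-' && y[k] == '-') continue;
        ++eligible;
        if (x[k] != y[k]) ++diff;
      }
      double v = eligible > 0 ? (double)diff / eligible : 0.0;
      d(i, j) = v; d(j, i) = v;
    }
  }
  return d;
}
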