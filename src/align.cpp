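#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Global alignment (Needleman-Wunsch with Gotoh affine gaps).
// Score: match +1, mismatch 0; a gap of length L costs open + L * extend.
// Traceback ties are broken deterministically: diagonal first, then gap in
// sequence 1 (consuming a residue of sequence 2), then gap in sequence 2.
// [[Rcpp::export]]
List cpp_nw_align(std::string s1, std::string s2, double match,
                  double mismatch, double open, double extend) {
  const int n = (int)s1.size(), m = (int)s2.size();
  const double NEG = -1e18, eps = 1e-9;
  // M: s1[i] aligned to s2[j]; X: gap in s1 (s2[j] unmatched);
  // Y: gap in s2 (s1[i] unmatched)
  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG)),
      X(n + 1, std::vector<double>(m + 1, NEG)),
      Y(n + 1, std::vector<double>(m + 1, NEG));
  M[0][0] = 0.0;
  for (int j = 1; j <= m; ++j) X[0][j] = -open - extend * j;
  for (int i = 1; i <= n; ++i) Y[i][0] = -open - extend * i;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (s1[i - 1] == s2[j - 1]) ? match : mismatch;
      double best = std::max(M[i - 1][j - 1],
                             std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = best + s;
      X[i][j] = std::max(M[i][j - 1] - open - extend, X[i][j - 1] - extend);
      Y[i][j] = std::max(std::max(M[i - 1][j] - open - extend,
                                  Y[i - 1][j] - extend),
                         X[i - 1][j] - open - extend);
    }
  }

  double score = std::max(M[n][m], std::max(X[n][m], Y[n][m]));

  std::vector<int> p1, p2;
  int i = n, j = m, state;
  if (std::abs(M[n][m] - score) < eps) state = 0;
  else if (std::abs(X[n][m] - score) < eps) state = 1;
  else state = 2;

  while (i > 0 || j > 0) {
    if (state == 0) {
      p1.push_back(i);
      p2.push_back(j);
      double s = (s1[i - 1] == s2[j - 1]) ? match : mismatch;
      double prev = M[i][j] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[i][j] - prev) < eps) state = 0;
      else if (std::abs(X[i][j] - prev) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      double here = X[i][j];
      --j;
      if (std::abs(M[i][j] - open - extend - here) < eps) state = 0;
      else state = 1; // X[i][j] - extend == here
    } else {
      double here = Y[i][j];
      --i;
      if (std::abs(M[i][j] - open - extend - here) < eps) state = 0;
      else if (std::abs(X[i][j] - open - extend - here) < eps) state = 1;
      else state = 2;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());

  int matches = 0;
  for (size_t k = 0; k < p1.size(); ++k)
    if (s1[p1[k] - 1] == s2[p2[k] - 1]) ++matches;

  return List::create(_["pos1"] = wrap(p1), _["pos2"] = wrap(p2),
                      _["score"] = score, _["n_match"] = matches);
}
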