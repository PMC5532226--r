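#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). Sequences arrive as 0-based integer
// codes indexing into the substitution matrix. Gap of length L costs
// gap_open + L * gap_extend.

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
              double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  double gini = gap_open + gap_extend;

  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = -(gap_open + i * gap_extend);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = -(gap_open + j * gap_extend);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double d = std::max(M(i - 1, j - 1),
                          std::max(Ix(i - 1, j - 1), Iy(i - 1, j - 1)));
      M(i, j) = d + s;
      Ix(i, j) = std::max(std::max(M(i - 1, j), Iy(i - 1, j)) - gini,
                          Ix(i - 1, j) - gap_extend);
      Iy(i, j) = std::max(std::max(M(i, j - 1), Ix(i, j - 1)) - gini,
                          Iy(i, j - 1) - gap_extend);
    }
  }
  double best = std::max(M(n, m), std::max(Ix(n, m), Iy(n, m)));

  // traceback; state preference M > Ix > Iy gives one deterministic optimum
  std::vector<int> ai, bi;  // emitted columns, -1 = gap
  int i = n, j = m;
  int state = (best == M(n, m)) ? 0 : (best == Ix(n, m) ? 1 : 2);
  while (i > 0 || j > 0) {
    if (state == 0) {
      double s = sub(a[i - 1], b[j - 1]);
      double tgt = M(i, j) - s;
      ai.push_back(a[i - 1]); bi.push_back(b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      state = (tgt == M(i, j)) ? 0 : (tgt == Ix(i, j) ? 1 : 2);
    } else if (state == 1) {
      double tgt = Ix(i, j);
      ai.push_back(a[i - 1]); bi.push_back(-1);
      --i;
      if (i == 0 && j == 0) break;
      if (tgt == Ix(i, j) - gap_extend) state = 1;
      else state = (tgt == M(i, j) - gini) ? 0 : 2;
    } else {
      double tgt = Iy(i, j);
      ai.push_back(-1); bi.push_back(b[j - 1]);
      --j;
      if (i == 0 && j == 0) break;
      if (tgt == Iy(i, j) - gap_extend) state = 2;
      else state = (tgt == M(i, j) - gini) ? 0 : 1;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best,
                      _["a"] = IntegerVector(ai.begin(), ai.end()),
                      _["b"] = IntegerVector(bi.begin(), bi.end()));
}

// [[Rcpp::export(name = ".sw_score")]]
double sw_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  double gini = gap_open + gap_extend;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0, F = NEG;  // diag = H[i-1][j-1]
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - gini, E[j] - gap_extend);        // gap in b
      F = std::max(H[j - 1] - gini, F - gap_extend);          // gap in a
      double h = diag + sub(a[i - 1], b[j - 1]);
      h = std::max(h, std::max(E[j], F));
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}
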