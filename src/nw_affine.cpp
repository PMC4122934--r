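#include <Rcpp.h>
using namespace Rcpp;

// Global (end-gap penalized) affine-gap alignment over a precomputed
// column-score matrix S (n x m), where S(i,j) is the score of aligning
// column i of profile A with column j of profile B.  A gap of length L
// costs open + ext * L.  Traceback ties prefer diagonal > up > left so
// the path is deterministic.
//
// Returns list(score, a, b): a and b are equal-length integer vectors of
// 1-based column indices with 0 marking a gap.
// [[Rcpp::export]]
List nw_affine_path(NumericMatrix S, double open, double ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // DP matrices: M (match), X (gap in B, consume A), Y (gap in A, consume B)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback state of each cell: which predecessor state was used
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(open + ext * i);
    tX(i, 0) = 1; // from X
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(open + ext * j);
    tY(0, j) = 2; // from Y
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: tie preference M(diag) > X > Y
      double bm = M(i - 1, j - 1); int sm = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); sm = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); sm = 2; }
      M(i, j) = bm + S(i - 1, j - 1); tM(i, j) = sm;
      // X: consume row i of A, gap in B (move "up")
      double ox = M(i - 1, j) - (open + ext);
      double ex = X(i - 1, j) - ext;
      double cx = Y(i - 1, j) - (open + ext);
      double bx = ox; int sx = 0;
      if (ex > bx) { bx = ex; sx = 1; }
      if (cx > bx) { bx = cx; sx = 2; }
      X(i, j) = bx; tX(i, j) = sx;
      // Y: consume column j of B, gap in A (move "left")
      double oy = M(i, j - 1) - (open + ext);
      double xy = X(i, j - 1) - (open + ext);
      double ey = Y(i, j - 1) - ext;
      double by = oy; int sy = 0;
      if (xy > by) { by = xy; sy = 1; }
      if (ey > by) { by = ey; sy = 2; }
      Y(i, j) = by; tY(i, j) = sy;
    }
  }
  // final state: prefer M > X > Y on ties
  int state = 0; double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i; state = prev;
    } else {
      int prev = tY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best,
                      _["a"] = IntegerVector(ai.begin(), ai.end()),
                      _["b"] = IntegerVector(bi.begin(), bi.end()));
}
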