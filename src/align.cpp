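#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) affine-gap alignment over a precomputed
// column-score matrix S (L1 x L2), as used for profile-profile merges in
// progressive multiple alignment. A gap of length L costs open + L * ext.
// Returns the move sequence from the alignment start:
//   1 = diagonal (consume a column of both profiles)
//   2 = up       (consume profile-A column, gap in profile B)
//   3 = left     (consume profile-B column, gap in profile A)
// [[Rcpp::export]]
IntegerVector profile_nw_path(NumericMatrix S, double open, double ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // three-state DP: M (match), X (gap in B, vertical), Y (gap in A, horizontal)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback state pointers: which state the max came from (0=M,1=X,2=Y)
  IntegerMatrix pm(n + 1, m + 1), px(n + 1, m + 1), py(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(open + i * ext);
    px(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(open + j * ext);
    py(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal move from any state
      double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
      int st = 0; double best = a;
      if (b > best) { best = b; st = 1; }
      if (c > best) { best = c; st = 2; }
      M(i, j) = best + S(i - 1, j - 1); pm(i, j) = st;
      // X: vertical (gap in B)
      double xo = M(i - 1, j) - open - ext;
      double xx = X(i - 1, j) - ext;
      double xy = Y(i - 1, j) - open - ext;
      st = 0; best = xo;
      if (xx > best) { best = xx; st = 1; }
      if (xy > best) { best = xy; st = 2; }
      X(i, j) = best; px(i, j) = st;
      // Y: horizontal (gap in A)
      double yo = M(i, j - 1) - open - ext;
      double yx = X(i, j - 1) - open - ext;
      double yy = Y(i, j - 1) - ext;
      st = 0; best = yo;
      if (yx > best) { best = yx; st = 1; }
      if (yy > best) { best = yy; st = 2; }
      Y(i, j) = best; py(i, j) = st;
    }
  }

  // traceback from (n, m), best of the three states
  int state = 0; double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }
  std::vector<int> rev;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      rev.push_back(1); state = pm(i, j); --i; --j;
    } else if (state == 1) {
      rev.push_back(2); state = px(i, j); --i;
    } else {
      rev.push_back(3); state = py(i, j); --j;
    }
  }
  IntegerVector out(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) out[k] = rev[rev.size() - 1 - k];
  return out;
}
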