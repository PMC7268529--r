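#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap global alignment over a precomputed column-score matrix
// cs (L1 x L2): cs(i,j) is the expected substitution score of aligning
// profile column i of the first group against column j of the second.
// Returns the traceback as a vector of ops: 1 = match (consume both),
// 2 = consume first profile only (gap in second), 3 = consume second only.
// [[Rcpp::export]]
IntegerVector profile_align_dp(NumericMatrix cs, double gap_open,
                               double gap_ext) {
  const int L1 = cs.nrow(), L2 = cs.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  NumericMatrix M(L1 + 1, L2 + 1), X(L1 + 1, L2 + 1), Y(L1 + 1, L2 + 1);
  // traceback state per matrix: which predecessor matrix fed it (0=M,1=X,2=Y)
  IntegerMatrix tM(L1 + 1, L2 + 1), tX(L1 + 1, L2 + 1), tY(L1 + 1, L2 + 1);

  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= L1; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -gap_open - gap_ext * (i - 1);
    tX(i, 0) = 1;
  }
  for (int j = 1; j <= L2; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -gap_open - gap_ext * (j - 1);
    tY(0, j) = 2;
  }
  for (int i = 1; i <= L1; ++i) {
    for (int j = 1; j <= L2; ++j) {
      // M: diagonal
      double m0 = M(i - 1, j - 1), m1 = X(i - 1, j - 1), m2 = Y(i - 1, j - 1);
      int am = (m0 >= m1 && m0 >= m2) ? 0 : (m1 >= m2 ? 1 : 2);
      double mb = (am == 0) ? m0 : (am == 1 ? m1 : m2);
      M(i, j) = mb + cs(i - 1, j - 1);
      tM(i, j) = am;
      // X: gap in second group (consume i)
      double x0 = M(i - 1, j) - gap_open, x1 = X(i - 1, j) - gap_ext;
      X(i, j) = (x0 >= x1) ? x0 : x1;
      tX(i, j) = (x0 >= x1) ? 0 : 1;
      // Y: gap in first group (consume j)
      double y0 = M(i, j - 1) - gap_open, y2 = Y(i, j - 1) - gap_ext;
      Y(i, j) = (y0 >= y2) ? y0 : y2;
      tY(i, j) = (y0 >= y2) ? 0 : 2;
    }
  }
  // traceback from the best end state
  int i = L1, j = L2;
  int state;
  if (M(i, j) >= X(i, j) && M(i, j) >= Y(i, j)) state = 0;
  else if (X(i, j) >= Y(i, j)) state = 1;
  else state = 2;
  std::vector<int> ops;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back(1);
      state = tM(i, j);
      --i; --j;
    } else if (state == 1) {
      ops.push_back(2);
      state = tX(i, j);
      --i;
    } else {
      ops.push_back(3);
      state = tY(i, j);
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}
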