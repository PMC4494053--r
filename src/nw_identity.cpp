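#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh recursion.
// match +1, mismatch -1; a gap of length g costs gapOpening + g * gapExtension.
// Returns the optimal score, the number of identical aligned pairs and the
// number of alignment columns outside terminal-gap runs of either sequence
// (the identity denominator).
static const double NEG = -1e30;

// [[Rcpp::export]]
List nw_identity_cpp(IntegerVector a, IntegerVector b,
                     double match = 1.0, double mismatch = -1.0,
                     double gap_open = 10.0, double gap_ext = 1.0) {
  const int n = a.size(), m = b.size();
  const double gi = -(gap_open + gap_ext);  // first gap residue
  const double ge = -gap_ext;               // each further residue
  const int W = m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG), X(M), Y(M);
  // back pointers: state entered from (0=M,1=X,2=Y); X = gap in b (a aligned
  // to '-'); Y = gap in a
  std::vector<signed char> BM((size_t)(n + 1) * W, -1), BX(BM), BY(BM);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    const size_t c = (size_t)i * W;
    X[c] = gi + ge * (i - 1);
    BX[c] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gi + ge * (j - 1);
    BY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    const size_t ro = (size_t)i * W, rp = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M
      double best = M[rp + j - 1]; signed char f = 0;
      if (X[rp + j - 1] > best) { best = X[rp + j - 1]; f = 1; }
      if (Y[rp + j - 1] > best) { best = Y[rp + j - 1]; f = 2; }
      M[ro + j] = best + s; BM[ro + j] = f;
      // X: consume a_i against a gap
      double x1 = M[rp + j] + gi, x2 = X[rp + j] + ge;
      if (x1 >= x2) { X[ro + j] = x1; BX[ro + j] = 0; }
      else          { X[ro + j] = x2; BX[ro + j] = 1; }
      // Y: consume b_j against a gap
      double y1 = M[ro + j - 1] + gi, y2 = Y[ro + j - 1] + ge;
      if (y1 >= y2) { Y[ro + j] = y1; BY[ro + j] = 0; }
      else          { Y[ro + j] = y2; BY[ro + j] = 2; }
    }
  }
  const size_t e = (size_t)n * W + m;
  double score = M[e]; int state = 0;
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }

  // traceback collecting column types: 0 = aligned pair, 1 = gap in b,
  // 2 = gap in a; record identity of aligned pairs
  std::vector<signed char> cols;
  std::vector<signed char> ident;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      cols.push_back(0);
      ident.push_back(a[i - 1] == b[j - 1] ? 1 : 0);
      state = BM[(size_t)i * W + j];
      --i; --j;
    } else if (state == 1) {
      cols.push_back(1);
      ident.push_back(0);
      state = BX[(size_t)i * W + j];
      --i;
    } else {
      cols.push_back(2);
      ident.push_back(0);
      state = BY[(size_t)i * W + j];
      --j;
    }
  }
  // cols is reversed; terminal-gap runs are at both ends
  int L = (int)cols.size();
  int lead = 0, trail = 0;
  while (lead < L && cols[L - 1 - lead] != 0) ++lead;      // front of alignment
  while (trail < L - lead && cols[trail] != 0) ++trail;    // back of alignment
  int kept = 0, matches = 0;
  for (int k = trail; k < L - lead; ++k) {
    ++kept;
    matches += ident[k];
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["columns"] = kept);
}
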