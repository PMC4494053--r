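#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local (Smith-Waterman-style) Viterbi over a profile with K match columns.
//
// lod : 20 x K matrix of match-emission log2-odds (log2(e_j(a)/bg(a)))
// tr  : 7 x K matrix of log2 transition probabilities out of match column j,
//       rows 0..6 = MM, MI, MD, IM, II, DM, DD
// seq : integer vector, residues coded 1..20
//
// Alignments must start and end in a match state; entry/exit are free.
// Insert emissions score 0 (background). Delete states emit nothing.
//
// Returns the optimal local hit (score, 1-based envelope, match count,
// residue position matched at every model column for realignment) and,
// if all_ends, the best hit ending at every sequence position (for
// repeat tiling).
static const double NEG = -1e30;

// [[Rcpp::export]]
List viterbi_local_cpp(NumericMatrix lod, NumericMatrix tr, IntegerVector seq,
                       bool all_ends = false) {
  const int K = lod.ncol();
  const int L = seq.size();
  const int W = K + 1;
  const size_t N = (size_t)(L + 1) * W;

  std::vector<double> VM(N, NEG), VI(N, NEG), VD(N, NEG);
  // back pointers: 0 = fresh start, 1 = from M, 2 = from I, 3 = from D
  std::vector<signed char> BM(N, -1), BI(N, -1), BD(N, -1);
  // carried along: start position of the local path, match-state count
  std::vector<int> SM(N, 0), SI(N, 0), SD(N, 0);
  std::vector<int> NMc(N, 0), NIc(N, 0), NDc(N, 0);

  NumericVector end_score(L, NEG);
  IntegerVector end_start(L, 0), end_nmatch(L, 0);

  double best = NEG;
  int bi = 0, bj = 0;

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1] - 1;
    const size_t ro = (size_t)i * W, rp = (size_t)(i - 1) * W;
    for (int j = 1; j <= K; ++j) {
      // --- match ---
      double e = lod(a, j - 1);
      double sc = 0.0; int from = 0, st = i, nm = 1;
      if (j > 1) {
        const size_t p = rp + (j - 1);
        double v = VM[p] + tr(0, j - 2);
        if (v > sc) { sc = v; from = 1; st = SM[p]; nm = NMc[p] + 1; }
        v = VI[p] + tr(3, j - 2);
        if (v > sc) { sc = v; from = 2; st = SI[p]; nm = NIc[p] + 1; }
        v = VD[p] + tr(5, j - 2);
        if (v > sc) { sc = v; from = 3; st = SD[p]; nm = NDc[p] + 1; }
      }
      const size_t c = ro + j;
      VM[c] = e + sc; BM[c] = (signed char)from; SM[c] = st; NMc[c] = nm;
      if (VM[c] > best) { best = VM[c]; bi = i; bj = j; }
      if (all_ends && VM[c] > end_score[i - 1]) {
        end_score[i - 1] = VM[c]; end_start[i - 1] = st; end_nmatch[i - 1] = nm;
      }
      // --- insert (after column j, j < K) ---
      if (j < K) {
        const size_t p = rp + j;
        double vI = VM[p] + tr(1, j - 1); int fI = 1;
        double v2 = VI[p] + tr(4, j - 1);
        if (v2 > vI) { vI = v2; fI = 2; }
        if (vI > NEG / 2) {
          VI[c] = vI; BI[c] = (signed char)fI;
          SI[c] = (fI == 1) ? SM[p] : SI[p];
          NIc[c] = (fI == 1) ? NMc[p] : NIc[p];
        }
      }
      // --- delete (same i, from column j-1) ---
      if (j > 1) {
        const size_t p = ro + (j - 1);
        double vD = VM[p] + tr(2, j - 2); int fD = 1;
        double v2 = VD[p] + tr(6, j - 2);
        if (v2 > vD) { vD = v2; fD = 3; }
        if (vD > NEG / 2) {
          VD[c] = vD; BD[c] = (signed char)fD;
          SD[c] = (fD == 1) ? SM[p] : SD[p];
          NDc[c] = (fD == 1) ? NMc[p] : NDc[p];
        }
      }
    }
  }

  IntegerVector match_path(K, 0);  // residue position matched at column j
  int env_start = 0, env_end = 0, cols_matched = 0, first_col = 0, last_col = 0;
  if (best > NEG / 2) {
    env_end = bi; last_col = bj;
    env_start = SM[(size_t)bi * W + bj];
    cols_matched = NMc[(size_t)bi * W + bj];
    // traceback from the best M cell
    int i = bi, j = bj, state = 1;  // 1=M, 2=I, 3=D
    while (true) {
      if (state == 1) {
        match_path[j - 1] = i;
        first_col = j;
        int from = BM[(size_t)i * W + j];
        if (from == 0) break;
        --i; --j; state = from;
      } else if (state == 2) {
        int from = BI[(size_t)i * W + j];
        --i; state = from;
      } else {
        int from = BD[(size_t)i * W + j];
        --j; state = from;
      }
    }
  }

  List out = List::create(
      _["score"] = (best > NEG / 2) ? best : R_NegInf,
      _["env_start"] = env_start, _["env_end"] = env_end,
      _["first_col"] = first_col, _["last_col"] = last_col,
      _["cols_matched"] = cols_matched, _["match_path"] = match_path);
  if (all_ends) {
    for (int i = 0; i < L; ++i)
      if (end_score[i] < NEG / 2) end_score[i] = R_NegInf;
    out["end_score"] = end_score;
    out["end_start"] = end_start;
    out["end_nmatch"] = end_nmatch;
  }
  return out;
}
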