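#include <Rcpp.h>
using namespace Rcpp;

static const double NEG = -1e30;

// Affine-gap profile-profile alignment with per-column gap costs.
//
// S(i,j): score for aligning column i of group A with column j of group B
// (residue substitution term plus any intron-position bonus, pre-weighted).
// openA/extA: cost of placing column i of A against a gap in B (gap open
// surcharge and per-column extension), already scaled by column occupancy
// and the opposing group's weight; likewise openB/extB.
//
// States: M (aligned columns), X (gap in B, consumes A), Y (gap in A,
// consumes B).  A gap's first column costs open + ext.  Ties are broken
// deterministically: M, then X (deletion), then Y (insertion).
//
// Optional second affine regime (long-gap): states X2/Y2 with open2 >=
// open and ext2 <= ext; each gap runs entirely in one regime and the
// better one wins.
// [[Rcpp::export(name = ".align_core")]]
List align_core(NumericMatrix S,
                NumericVector openA, NumericVector extA,
                NumericVector openB, NumericVector extB,
                bool double_affine,
                NumericVector openA2, NumericVector extA2,
                NumericVector openB2, NumericVector extB2) {
  const int la = S.nrow(), lb = S.ncol();
  const int nst = double_affine ? 5 : 3; // M,X,Y[,X2,Y2]
  std::vector<NumericMatrix> V;
  std::vector<IntegerMatrix> B; // backpointer: predecessor state + 1 (0 = start)
  for (int s = 0; s < nst; s++) {
    NumericMatrix v(la + 1, lb + 1);
    std::fill(v.begin(), v.end(), NEG);
    V.push_back(v);
    B.push_back(IntegerMatrix(la + 1, lb + 1));
  }
  V[0](0, 0) = 0.0;

  for (int i = 0; i <= la; i++) {
    for (int j = 0; j <= lb; j++) {
      if (i == 0 && j == 0) continue;
      // M: diagonal
      if (i > 0 && j > 0) {
        double s = S(i - 1, j - 1);
        double best = NEG; int bs = 0;
        for (int p = 0; p < nst; p++) {
          double c = V[p](i - 1, j - 1);
          if (c > best) { best = c; bs = p + 1; }
        }
        if (best > NEG) { V[0](i, j) = best + s; B[0](i, j) = bs; }
      }
      // X: consume A column i-1 against gap in B
      if (i > 0) {
        double o = openA[i - 1], e = extA[i - 1];
        double best = NEG; int bs = 0;
        for (int p = 0; p < nst; p++) {
          double c = V[p](i - 1, j);
          if (c <= NEG) continue;
          c -= (p == 1) ? e : (o + e); // continuing X extends; else open
          if (c > best) { best = c; bs = p + 1; }
        }
        if (best > NEG) { V[1](i, j) = best; B[1](i, j) = bs; }
        if (double_affine) {
          double o2 = openA2[i - 1], e2 = extA2[i - 1];
          double best2 = NEG; int bs2 = 0;
          for (int p = 0; p < nst; p++) {
            double c = V[p](i - 1, j);
            if (c <= NEG) continue;
            c -= (p == 3) ? e2 : (o2 + e2);
            if (c > best2) { best2 = c; bs2 = p + 1; }
          }
          if (best2 > NEG) { V[3](i, j) = best2; B[3](i, j) = bs2; }
        }
      }
      // Y: consume B column j-1 against gap in A
      if (j > 0) {
        double o = openB[j - 1], e = extB[j - 1];
        double best = NEG; int bs = 0;
        for (int p = 0; p < nst; p++) {
          double c = V[p](i, j - 1);
          if (c <= NEG) continue;
          c -= (p == 2) ? e : (o + e);
          if (c > best) { best = c; bs = p + 1; }
        }
        if (best > NEG) { V[2](i, j) = best; B[2](i, j) = bs; }
        if (double_affine) {
          double o2 = openB2[j - 1], e2 = extB2[j - 1];
          double best2 = NEG; int bs2 = 0;
          for (int p = 0; p < nst; p++) {
            double c = V[p](i, j - 1);
            if (c <= NEG) continue;
            c -= (p == 4) ? e2 : (o2 + e2);
            if (c > best2) { best2 = c; bs2 = p + 1; }
          }
          if (best2 > NEG) { V[4](i, j) = best2; B[4](i, j) = bs2; }
        }
      }
    }
  }

  // terminal cell: prefer M, X, Y (then X2, Y2)
  double score = NEG; int st = 0;
  for (int p = 0; p < nst; p++) {
    if (V[p](la, lb) > score) { score = V[p](la, lb); st = p; }
  }

  // traceback
  std::vector<int> ops; // 1 = diagonal, 2 = consume A, 3 = consume B
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int prev = B[st](i, j) - 1;
    if (st == 0) { ops.push_back(1); i--; j--; }
    else if (st == 1 || st == 3) { ops.push_back(2); i--; }
    else { ops.push_back(3); j--; }
    st = prev;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = wrap(ops));
}

// Exhaustive enumeration oracle for pairwise global affine alignment of two
// single sequences: recursively walks every monotone alignment path and
// returns the best score.  Independent of the DP above (no memoisation).
static double enum_rec(const NumericMatrix& S, int i, int j, int st,
                       double gapo, double gape, int la, int lb) {
  if (i == la && j == lb) return 0.0;
  double best = NEG;
  if (i < la && j < lb) {
    double v = S(i, j) + enum_rec(S, i + 1, j + 1, 0, gapo, gape, la, lb);
    if (v > best) best = v;
  }
  if (i < la) {
    double v = -((st == 1) ? 0.0 : gapo) - gape +
      enum_rec(S, i + 1, j, 1, gapo, gape, la, lb);
    if (v > best) best = v;
  }
  if (j < lb) {
    double v = -((st == 2) ? 0.0 : gapo) - gape +
      enum_rec(S, i, j + 1, 2, gapo, gape, la, lb);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export(name = ".enum_pair_align")]]
double enum_pair_align(NumericMatrix S, double gap_open, double gap_ext) {
  return enum_rec(S, 0, 0, 0, gap_open, gap_ext, S.nrow(), S.ncol());
}
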