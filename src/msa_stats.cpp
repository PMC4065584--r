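#include <Rcpp.h>
using namespace Rcpp;

// Sum-of-pairs statistics of a gene-structure-aware alignment.
//
// aln: n x L integer codes (0..20 residues, -1 gap).
// pairW: n x n pair weights (used for the weighted totals and the
//   per-column scores).
// M: 21 x 21 substitution matrix.
// intron marks: parallel vectors (member row 0-based, column 1-based,
//   phase) -- a pair of marks at the same column and phase earns
//   `bonus` once per sequence pair.
// Gap runs are scored affinely per pair (open + ext * len; with the
// double-affine option each run takes the cheaper regime); columns
// gapped in both rows are skipped and do not interrupt a run.
//
// Returns: SP total, WSP total, and the per-column weighted
// substitution score (for conserved-block detection).
// [[Rcpp::export(name = ".wsp_stats")]]
List wsp_stats(IntegerMatrix aln, NumericMatrix pairW, NumericMatrix M,
               double gap_open, double gap_ext,
               bool double_affine, double gap_open2, double gap_ext2,
               IntegerVector mk_row, IntegerVector mk_col,
               IntegerVector mk_phase, double bonus) {
  const int n = aln.nrow(), L = aln.ncol();
  NumericVector colscore(L);
  double sp = 0.0, wsp = 0.0;

  // intron mark lookup: key = column * 3 + phase per member
  std::vector<std::vector<long> > marks(n);
  for (int k = 0; k < mk_row.size(); k++) {
    marks[mk_row[k]].push_back((long)mk_col[k] * 3L + mk_phase[k]);
  }
  for (int i = 0; i < n; i++) std::sort(marks[i].begin(), marks[i].end());

  for (int i = 0; i < n - 1; i++) {
    for (int j = i + 1; j < n; j++) {
      double w = pairW(i, j);
      double s = 0.0;
      int run = 0; // current single-side gap run length
      for (int c = 0; c < L; c++) {
        int a = aln(i, c), b = aln(j, c);
        if (a < 0 && b < 0) continue;       // both gapped: ignore
        if (a < 0 || b < 0) { run++; continue; }
        if (run > 0) {
          double g = gap_open + gap_ext * run;
          if (double_affine) {
            double g2 = gap_open2 + gap_ext2 * run;
            if (g2 < g) g = g2;
          }
          s -= g;
          run = 0;
        }
        double sub = M(a, b);
        s += sub;
        colscore[c] += w * sub;
      }
      if (run > 0) {
        double g = gap_open + gap_ext * run;
        if (double_affine) {
          double g2 = gap_open2 + gap_ext2 * run;
          if (g2 < g) g = g2;
        }
        s -= g;
      }
      // shared intron marks
      if (!marks[i].empty() && !marks[j].empty()) {
        size_t u = 0, v = 0;
        while (u < marks[i].size() && v < marks[j].size()) {
          if (marks[i][u] == marks[j][v]) { s += bonus; u++; v++; }
          else if (marks[i][u] < marks[j][v]) u++;
          else v++;
        }
      }
      sp += s;
      wsp += w * s;
    }
  }
  return List::create(_["sp"] = sp, _["wsp"] = wsp,
                      _["colscore"] = colscore);
}

// Per-region average divergence of each member from the rest: for every
// pair and region, the number of aligned residue columns and the number
// of mismatches among them.
// regions: r x 2 matrix of 0-based half-open column intervals.
// Returns an n x r matrix of mean pairwise mismatch fractions (NA where
// a member shares no aligned column with anyone in the region).
// [[Rcpp::export(name = ".divergence_stats")]]
NumericMatrix divergence_stats(IntegerMatrix aln, IntegerMatrix regions) {
  const int n = aln.nrow(), R = regions.nrow();
  NumericMatrix out(n, R);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int r = 0; r < R; r++) {
    int c0 = regions(r, 0), c1 = regions(r, 1);
    std::vector<double> sum(n, 0.0);
    std::vector<int> cnt(n, 0);
    for (int i = 0; i < n - 1; i++) {
      for (int j = i + 1; j < n; j++) {
        int both = 0, mism = 0;
        for (int c = c0; c < c1; c++) {
          int a = aln(i, c), b = aln(j, c);
          if (a < 0 || b < 0) continue;
          both++;
          if (a != b) mism++;
        }
        if (both > 0) {
          double f = (double)mism / both;
          sum[i] += f; cnt[i]++;
          sum[j] += f; cnt[j]++;
        }
      }
    }
    for (int i = 0; i < n; i++) {
      if (cnt[i] > 0) out(i, r) = sum[i] / cnt[i];
    }
  }
  return out;
}
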