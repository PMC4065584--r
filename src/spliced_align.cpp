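#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double NEG = -1e30;

// Spliced alignment of a genomic window (DNA) against a protein or
// generalized-profile template.
//
// dna: window nucleotides coded 0=A,1=C,2=G,3=T,4=other.
// codon_table: length 125, index n1*25+n2*5+n3 -> 0..19 amino acid,
//   20 = X (ambiguous), 21 = stop.
// PS: 21 x P matrix, PS(a, j) = score of residue code a (X = 20) against
//   template column j.
// bonus: 3 x P, reward for predicting an intron of phase p whose host
//   residue is template column j (already scaled by the intron-frequency
//   of the template and the bonus size b).
// pg_open/pg_ext: per-template-column costs of deleting that column.
// dg_open/dg_ext: affine cost of inserting one genomic codon not matched
//   to the template (in-frame DNA insertion).
// fs_pen: surcharge for a codon consuming 3+delta nt, delta in
//   {-2,-1,+1,+2} (frameshift); only if allow_fs.
// stop_pen: surcharge for an in-frame stop codon kept inside an exon.
// Introns: GT..AG only, length >= min_intron, cost intron_open +
//   intron_logext * log(length); alignment is global in the template and
//   local in the window (free leading/trailing DNA).
//
// States per (i nt consumed, j residues): M at codon boundary, Pg
// (template column deleted), Ng (genomic codon inserted).  An intron of
// phase p interrupts the codon of the residue being created after p nt;
// its host residue (aa_index, 0-based) is j-1 for every phase, matching
// the convention that a phase-0 intron is attached to the following
// residue.
// [[Rcpp::export(name = ".spliced_core")]]
List spliced_core(IntegerVector dna, IntegerVector codon_table,
                  NumericMatrix PS, NumericMatrix bonus,
                  NumericVector pg_open, NumericVector pg_ext,
                  double dg_open, double dg_ext,
                  double fs_pen, double stop_pen, bool allow_fs,
                  double intron_open, double intron_logext,
                  int min_intron) {
  const int N = dna.size(), P = PS.ncol();
  if (min_intron < 4) min_intron = 4;

  NumericMatrix M(N + 1, P + 1), Pg(N + 1, P + 1), Ng(N + 1, P + 1);
  // op codes -- M: 1..5 codon of that length, 10+p intron of phase p,
  //             -1 start; Pg/Ng: 1 open-from-M, 2 open-from-other, 3 extend
  IntegerMatrix opM(N + 1, P + 1), opP(N + 1, P + 1), opN(N + 1, P + 1);
  IntegerMatrix auxM(N + 1, P + 1);  // donor position for intron ops
  IntegerMatrix prM(N + 1, P + 1);   // predecessor state (1=M,2=Pg,3=Ng)
  std::fill(M.begin(), M.end(), NEG);
  std::fill(Pg.begin(), Pg.end(), NEG);
  std::fill(Ng.begin(), Ng.end(), NEG);

  for (int i = 0; i <= N; i++) { M(i, 0) = 0.0; opM(i, 0) = -1; }

  std::vector<int> donors, acceptors;
  for (int d = 0; d + 1 < N; d++)
    if (dna[d] == 2 && dna[d + 1] == 3) donors.push_back(d);       // GT
  for (int a = 2; a <= N; a++)
    if (dna[a - 2] == 0 && dna[a - 1] == 2) acceptors.push_back(a); // ..AG

  auto aa_of = [&](int p1, int p2, int p3) {
    int n1 = dna[p1], n2 = dna[p2], n3 = dna[p3];
    return codon_table[n1 * 25 + n2 * 5 + n3];
  };
  auto res_score = [&](int aa, int jcol) {
    double v = PS(aa == 21 ? 20 : aa, jcol);
    if (aa == 21) v -= stop_pen;
    return v;
  };

  std::vector<int> lens;
  lens.push_back(3);
  if (allow_fs) { lens.push_back(2); lens.push_back(4);
                  lens.push_back(1); lens.push_back(5); }

  for (int j = 1; j <= P; j++) {
    // intron transitions into column j (source column j-1 is complete)
    for (size_t ai = 0; ai < acceptors.size(); ai++) {
      int a = acceptors[ai];
      for (size_t di = 0; di < donors.size(); di++) {
        int d = donors[di];
        int len = a - d;
        if (len < min_intron) continue;
        double ipen = intron_open + intron_logext * std::log((double)len);
        for (int p = 0; p < 3; p++) {
          int is = d - p, it = a + 3 - p;
          if (is < 0 || it > N) continue;
          double src = M(is, j - 1); int ps = 1;
          if (Pg(is, j - 1) > src) { src = Pg(is, j - 1); ps = 2; }
          if (Ng(is, j - 1) > src) { src = Ng(is, j - 1); ps = 3; }
          if (src <= NEG) continue;
          int aa;
          // split codon: p nt before the donor, 3-p nt after the acceptor
          if (p == 0)      aa = aa_of(a, a + 1, a + 2);
          else if (p == 1) aa = aa_of(d - 1, a, a + 1);
          else             aa = aa_of(d - 2, d - 1, a);
          double v = src + res_score(aa, j - 1) - ipen + bonus(p, j - 1);
          if (v > M(it, j)) {
            M(it, j) = v; opM(it, j) = 10 + p;
            auxM(it, j) = d; prM(it, j) = ps;
          }
        }
      }
    }
    for (int i = 0; i <= N; i++) {
      // M: plain (possibly frameshifted) codon emission
      for (size_t li = 0; li < lens.size(); li++) {
        int L = lens[li];
        if (i - L < 0) continue;
        double src = M(i - L, j - 1); int ps = 1;
        if (Pg(i - L, j - 1) > src) { src = Pg(i - L, j - 1); ps = 2; }
        if (Ng(i - L, j - 1) > src) { src = Ng(i - L, j - 1); ps = 3; }
        if (src <= NEG) continue;
        int aa = (L >= 3) ? aa_of(i - 3, i - 2, i - 1) : 20;
        double v = src + res_score(aa, j - 1);
        if (L != 3) v -= fs_pen;
        if (v > M(i, j)) {
          M(i, j) = v; opM(i, j) = L; auxM(i, j) = 0; prM(i, j) = ps;
        }
      }
      // Pg: delete template column j-1
      {
        double vo = std::max(M(i, j - 1), Ng(i, j - 1));
        int oo = (M(i, j - 1) >= Ng(i, j - 1)) ? 1 : 2;
        double best = NEG; int op = 0;
        if (vo > NEG) { best = vo - pg_open[j - 1] - pg_ext[j - 1]; op = oo; }
        if (Pg(i, j - 1) > NEG) {
          double ve = Pg(i, j - 1) - pg_ext[j - 1];
          if (ve > best) { best = ve; op = 3; }
        }
        if (best > NEG) { Pg(i, j) = best; opP(i, j) = op; }
      }
      // Ng: insert one genomic codon (no template column)
      if (i >= 3) {
        int aa = aa_of(i - 3, i - 2, i - 1);
        double extra = (aa == 21) ? stop_pen : 0.0;
        double vo = std::max(M(i - 3, j), Pg(i - 3, j));
        int oo = (M(i - 3, j) >= Pg(i - 3, j)) ? 1 : 2;
        double best = NEG; int op = 0;
        if (vo > NEG) { best = vo - dg_open - dg_ext - extra; op = oo; }
        if (Ng(i - 3, j) > NEG) {
          double ve = Ng(i - 3, j) - dg_ext - extra;
          if (ve > best) { best = ve; op = 3; }
        }
        if (best > NEG) { Ng(i, j) = best; opN(i, j) = op; }
      }
    }
  }

  // best end: global in template, free trailing DNA; prefer M over Pg,
  // and the smallest end position on ties
  double score = NEG; int ei = -1, est_state = 1;
  for (int i = 0; i <= N; i++) {
    if (M(i, P) > score) { score = M(i, P); ei = i; est_state = 1; }
  }
  for (int i = 0; i <= N; i++) {
    if (Pg(i, P) > score) { score = Pg(i, P); ei = i; est_state = 2; }
  }
  if (ei < 0 || score <= NEG)
    return List::create(_["ok"] = false, _["score"] = NEG);

  // traceback
  std::vector<std::pair<int, int> > coding;  // nt spans
  std::vector<int> in_d, in_a, in_aa, in_ph; // introns
  std::vector<int> fs_pos, fs_off;           // frameshifts
  std::vector<int> stop_res;                 // template columns with stops
  int n_matched = 0;
  int i = ei, j = P, st = est_state;
  int start = ei;
  while (!(st == 1 && opM(i, j) == -1)) {
    if (st == 1) {
      int op = opM(i, j);
      if (op >= 10) { // intron, phase p
        int p = op - 10, d = auxM(i, j), a = i - (3 - p);
        in_d.push_back(d); in_a.push_back(a);
        in_aa.push_back(j - 1); in_ph.push_back(p);
        if (bonus(p, j - 1) > 0) n_matched++;
        if (p > 0) coding.push_back(std::make_pair(d - p, d));
        coding.push_back(std::make_pair(a, i));
        int aa;
        if (p == 0)      aa = aa_of(a, a + 1, a + 2);
        else if (p == 1) aa = aa_of(d - 1, a, a + 1);
        else             aa = aa_of(d - 2, d - 1, a);
        if (aa == 21) stop_res.push_back(j - 1);
        st = prM(i, j); i = d - p; j--;
      } else {
        int L = op;
        coding.push_back(std::make_pair(i - L, i));
        if (L != 3) { fs_pos.push_back(i - L); fs_off.push_back(L - 3); }
        if (L >= 3 && aa_of(i - 3, i - 2, i - 1) == 21)
          stop_res.push_back(j - 1);
        st = prM(i, j); i -= L; j--;
      }
    } else if (st == 2) {
      int op = opP(i, j);
      st = (op == 1) ? 1 : (op == 2 ? 3 : 2);
      j--;
    } else {
      int op = opN(i, j);
      coding.push_back(std::make_pair(i - 3, i));
      if (aa_of(i - 3, i - 2, i - 1) == 21) stop_res.push_back(j - 1);
      st = (op == 1) ? 1 : (op == 2 ? 2 : 3);
      i -= 3;
    }
    start = i;
  }

  // merge coding spans (collected back-to-front) into exon intervals
  std::sort(coding.begin(), coding.end());
  std::vector<int> ex_s, ex_e;
  for (size_t k = 0; k < coding.size(); k++) {
    if (coding[k].first == coding[k].second) continue;
    if (!ex_s.empty() && coding[k].first <= ex_e.back())
      ex_e.back() = std::max(ex_e.back(), coding[k].second);
    else { ex_s.push_back(coding[k].first); ex_e.push_back(coding[k].second); }
  }
  std::reverse(in_d.begin(), in_d.end());
  std::reverse(in_a.begin(), in_a.end());
  std::reverse(in_aa.begin(), in_aa.end());
  std::reverse(in_ph.begin(), in_ph.end());
  std::reverse(fs_pos.begin(), fs_pos.end());
  std::reverse(fs_off.begin(), fs_off.end());

  return List::create(
    _["ok"] = true, _["score"] = score, _["start"] = start,
    _["exon_start"] = wrap(ex_s), _["exon_end"] = wrap(ex_e),
    _["intron_donor"] = wrap(in_d), _["intron_acceptor"] = wrap(in_a),
    _["intron_aa"] = wrap(in_aa), _["intron_phase"] = wrap(in_ph),
    _["fs_pos"] = wrap(fs_pos), _["fs_off"] = wrap(fs_off),
    _["stop_cols"] = wrap(stop_res),
    _["n_template_intron_matches"] = n_matched);
}

// ---------------------------------------------------------------------------
// Exhaustive oracle: enumerate every gene structure (window start + every
// compatible chain of GT..AG introns) and, for each, score the spliced CDS
// against the template with a plain affine codon-level alignment in which
// junction codons are forced to be matched.  Frameshifts are not modelled.
// Independent of the state machine above.

struct OracleCtx {
  const IntegerVector* dna;
  const IntegerVector* ct;
  const NumericMatrix* PS;
  const NumericMatrix* bonus;
  const NumericVector* pgo;
  const NumericVector* pge;
  double dgo, dge, stop_pen, intron_open, intron_logext;
  int N, P;
};

static double score_structure(const OracleCtx& C, int s,
                              const std::vector<std::pair<int, int> >& intr) {
  const IntegerVector& dna = *C.dna;
  // spliced CDS positions
  std::vector<int> cds;
  int pos = s;
  for (size_t k = 0; k < intr.size(); k++) {
    if (intr[k].first < pos) return NEG;
    for (int q = pos; q < intr[k].first; q++) cds.push_back(q);
    pos = intr[k].second;
  }
  for (int q = pos; q < C.N; q++) cds.push_back(q);
  int ncod = (int)cds.size() / 3;
  if (ncod < 1) return NEG;

  // junction codons and phases; reject structures sharing a codon
  std::vector<int> jphase(ncod, -1);
  double ipen_total = 0.0;
  int cum = 0, prev_end = s;
  for (size_t k = 0; k < intr.size(); k++) {
    cum += intr[k].first - prev_end;
    prev_end = intr[k].second;
    int c = cum / 3, p = cum % 3;
    if (c >= ncod) return NEG;          // junction codon incomplete
    if (jphase[c] >= 0) return NEG;     // two introns in one codon
    jphase[c] = p;
    int len = intr[k].second - intr[k].first;
    ipen_total += C.intron_open + C.intron_logext * std::log((double)len);
  }

  std::vector<int> aa(ncod);
  for (int c = 0; c < ncod; c++) {
    int n1 = dna[cds[3 * c]], n2 = dna[cds[3 * c + 1]], n3 = dna[cds[3 * c + 2]];
    aa[c] = (*C.ct)[n1 * 25 + n2 * 5 + n3];
  }

  const int P = C.P;
  std::vector<std::vector<double> > M(ncod + 1, std::vector<double>(P + 1, NEG)),
    Pg(ncod + 1, std::vector<double>(P + 1, NEG)),
    Ng(ncod + 1, std::vector<double>(P + 1, NEG));
  M[0][0] = 0.0;
  for (int c = 0; c <= ncod; c++) {
    for (int j = 0; j <= P; j++) {
      if (c > 0 && j > 0) {
        double src = std::max(M[c - 1][j - 1],
                              std::max(Pg[c - 1][j - 1], Ng[c - 1][j - 1]));
        if (src > NEG) {
          int a = aa[c - 1];
          double v = src + (*C.PS)(a == 21 ? 20 : a, j - 1);
          if (a == 21) v -= C.stop_pen;
          if (jphase[c - 1] >= 0) v += (*C.bonus)(jphase[c - 1], j - 1);
          M[c][j] = v;
        }
      }
      if (j > 0) {
        double vo = std::max(M[c][j - 1], Ng[c][j - 1]);
        double best = NEG;
        if (vo > NEG) best = vo - (*C.pgo)[j - 1] - (*C.pge)[j - 1];
        if (Pg[c][j - 1] > NEG)
          best = std::max(best, Pg[c][j - 1] - (*C.pge)[j - 1]);
        Pg[c][j] = best;
      }
      if (c > 0 && j > 0 && jphase[c - 1] < 0) { // junction codons: no skip
        double extra = (aa[c - 1] == 21) ? C.stop_pen : 0.0;
        double vo = std::max(M[c - 1][j], Pg[c - 1][j]);
        double best = NEG;
        if (vo > NEG) best = vo - C.dgo - C.dge - extra;
        if (Ng[c - 1][j] > NEG)
          best = std::max(best, Ng[c - 1][j] - C.dge - extra);
        Ng[c][j] = best;
      }
    }
  }
  double best = NEG;
  for (int c = 0; c <= ncod; c++)
    best = std::max(best, std::max(M[c][P], Pg[c][P]));
  if (best <= NEG) return NEG;
  return best - ipen_total;
}

static void enum_chains(const OracleCtx& C, int s,
                        const std::vector<std::pair<int, int> >& pairs,
                        size_t from, std::vector<std::pair<int, int> >& cur,
                        double& best) {
  double v = score_structure(C, s, cur);
  if (v > best) best = v;
  for (size_t k = from; k < pairs.size(); k++) {
    if (pairs[k].first < s) continue;
    if (!cur.empty() && pairs[k].first < cur.back().second) continue;
    cur.push_back(pairs[k]);
    enum_chains(C, s, pairs, k + 1, cur, best);
    cur.pop_back();
  }
}

// [[Rcpp::export(name = ".enum_spliced")]]
double enum_spliced(IntegerVector dna, IntegerVector codon_table,
                    NumericMatrix PS, NumericMatrix bonus,
                    NumericVector pg_open, NumericVector pg_ext,
                    double dg_open, double dg_ext, double stop_pen,
                    double intron_open, double intron_logext,
                    int min_intron) {
  OracleCtx C;
  C.dna = &dna; C.ct = &codon_table; C.PS = &PS; C.bonus = &bonus;
  C.pgo = &pg_open; C.pge = &pg_ext;
  C.dgo = dg_open; C.dge = dg_ext; C.stop_pen = stop_pen;
  C.intron_open = intron_open; C.intron_logext = intron_logext;
  C.N = dna.size(); C.P = PS.ncol();
  if (min_intron < 4) min_intron = 4;

  std::vector<std::pair<int, int> > pairs;
  for (int d = 0; d + 1 < C.N; d++) {
    if (!(dna[d] == 2 && dna[d + 1] == 3)) continue;
    for (int a = d + min_intron; a <= C.N; a++)
      if (dna[a - 2] == 0 && dna[a - 1] == 2)
        pairs.push_back(std::make_pair(d, a));
  }
  std::sort(pairs.begin(), pairs.end());

  double best = NEG;
  std::vector<std::pair<int, int> > cur;
  for (int s = 0; s < C.N; s++) enum_chains(C, s, pairs, 0, cur, best);
  return best;
}
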