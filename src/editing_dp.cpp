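// Constrained affine three-state dynamic program for U-indel editing
// reconstruction. States: M (diagonal), I (U-insertion run: gap in the gene,
// admissible only where the mRNA character is T), D (U-deletion run: gap in
// the mRNA, admissible only where the gene character is T). Diagonal pairs are
// scored as match, deaminative substitution (gene C vs mRNA T, gene A vs mRNA
// G) or other-mismatch (optionally disallowed); N never matches. Run cost is
// open for the first base and ext for each further base. With end_free_gene,
// leading/trailing gene characters are skipped at no cost (the mRNA is always
// aligned end to end).
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static const double NEG = -1e18;

// [[Rcpp::export(name = ".editing_dp")]]
List editing_dp(std::string gene, std::string mrna,
                double match, double deam_sub, double other_mismatch,
                bool allow_other,
                double ins_open, double ins_ext,
                double del_open, double del_ext,
                bool end_free_gene) {
  const int n = gene.size(), m = mrna.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const R_xlen_t ncell = (R_xlen_t)(n + 1) * (m + 1);
  if (ncell > 60000000) stop("sequences too long for full DP");

  std::vector<double> M(ncell, NEG), I(ncell, NEG), D(ncell, NEG);
  // traceback codes: 0 = from start (free base), 1 = M, 2 = I, 3 = D
  std::vector<uint8_t> tM(ncell, 0), tI(ncell, 0), tD(ncell, 0);
  auto ix = [m](int i, int j) { return (R_xlen_t)i * (m + 1) + j; };

  auto pair_score = [&](char g, char c) -> double {
    if (g == c && g != 'N') return match;
    if (g == 'C' && c == 'T') return deam_sub;
    if (g == 'A' && c == 'G') return deam_sub;
    return allow_other ? other_mismatch : NEG;
  };
  // free start base available at (i, 0)?
  auto base_ok = [&](int i) { return end_free_gene || i == 0; };

  // column j == 0: deletion runs before any mRNA is consumed
  for (int i = 1; i <= n; ++i) {
    if (gene[i - 1] != 'T') continue;
    double open_sc = base_ok(i - 1) ? del_open : NEG;
    double ext_sc = (D[ix(i - 1, 0)] > NEG / 2) ? D[ix(i - 1, 0)] + del_ext : NEG;
    if (open_sc >= ext_sc) {
      if (open_sc > NEG / 2) { D[ix(i, 0)] = open_sc; tD[ix(i, 0)] = 0; }
    } else {
      D[ix(i, 0)] = ext_sc; tD[ix(i, 0)] = 3;
    }
  }

  for (int j = 1; j <= m; ++j) {
    const char c = mrna[j - 1];
    const bool insOK = (c == 'T');
    // row i == 0
    if (insOK) {
      double open_sc = (j == 1) ? ins_open : NEG; // base only at (0, 0)
      double ext_sc = (I[ix(0, j - 1)] > NEG / 2) ? I[ix(0, j - 1)] + ins_ext : NEG;
      if (open_sc >= ext_sc) {
        if (open_sc > NEG / 2) { I[ix(0, j)] = open_sc; tI[ix(0, j)] = 0; }
      } else { I[ix(0, j)] = ext_sc; tI[ix(0, j)] = 2; }
    }
    for (int i = 1; i <= n; ++i) {
      const char g = gene[i - 1];
      // M
      double ps = pair_score(g, c);
      if (ps > NEG / 2) {
        double bM = M[ix(i - 1, j - 1)], bI = I[ix(i - 1, j - 1)], bD = D[ix(i - 1, j - 1)];
        double bB = (j - 1 == 0 && base_ok(i - 1)) ? 0.0 : NEG;
        double best = bM; uint8_t tb = 1;
        if (bD > best) { best = bD; tb = 3; }
        if (bI > best) { best = bI; tb = 2; }
        if (bB > best) { best = bB; tb = 0; }
        if (best > NEG / 2) { M[ix(i, j)] = ps + best; tM[ix(i, j)] = tb; }
      }
      // I (consume mRNA T)
      if (insOK) {
        double oM = M[ix(i, j - 1)], oD = D[ix(i, j - 1)], eI = I[ix(i, j - 1)];
        double oB = (j - 1 == 0 && base_ok(i)) ? 0.0 : NEG;
        double best = NEG; uint8_t tb = 1;
        if (oM > NEG / 2 && oM + ins_open > best) { best = oM + ins_open; tb = 1; }
        if (oD > NEG / 2 && oD + ins_open > best) { best = oD + ins_open; tb = 3; }
        if (eI > NEG / 2 && eI + ins_ext > best) { best = eI + ins_ext; tb = 2; }
        if (oB > NEG / 2 && oB + ins_open > best) { best = oB + ins_open; tb = 0; }
        if (best > NEG / 2) { I[ix(i, j)] = best; tI[ix(i, j)] = tb; }
      }
      // D (consume gene T)
      if (g == 'T') {
        double oM = M[ix(i - 1, j)], oI = I[ix(i - 1, j)], eD = D[ix(i - 1, j)];
        double best = NEG; uint8_t tb = 1;
        if (oM > NEG / 2 && oM + del_open > best) { best = oM + del_open; tb = 1; }
        if (oI > NEG / 2 && oI + del_open > best) { best = oI + del_open; tb = 2; }
        if (eD > NEG / 2 && eD + del_ext > best) { best = eD + del_ext; tb = 3; }
        if (best > NEG / 2) { D[ix(i, j)] = best; tD[ix(i, j)] = tb; }
      }
    }
  }

  // terminal cell: global in mRNA; gene end free if end_free_gene
  double best = NEG; int bi = -1; uint8_t bstate = 1;
  int ilo = end_free_gene ? 0 : n, ihi = n;
  for (int i = ilo; i <= ihi; ++i) {
    // preference order M > D > I for deterministic tie-breaking
    if (M[ix(i, m)] > best) { best = M[ix(i, m)]; bi = i; bstate = 1; }
    if (D[ix(i, m)] > best) { best = D[ix(i, m)]; bi = i; bstate = 3; }
    if (I[ix(i, m)] > best) { best = I[ix(i, m)]; bi = i; bstate = 2; }
  }
  if (best < NEG / 2) {
    return List::create(_["unalignable"] = true, _["score"] = NA_REAL,
                        _["ops"] = "", _["gene_start"] = IntegerVector::get_na(),
                        _["gene_end"] = IntegerVector::get_na());
  }

  // traceback
  std::string ops;
  int i = bi, j = m;
  uint8_t st = bstate;
  while (true) {
    uint8_t prev;
    if (st == 1) { prev = tM[ix(i, j)]; ops.push_back('M'); --i; --j; }
    else if (st == 2) { prev = tI[ix(i, j)]; ops.push_back('I'); --j; }
    else { prev = tD[ix(i, j)]; ops.push_back('D'); --i; }
    if (prev == 0) break;
    st = prev;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["unalignable"] = false, _["score"] = best,
                      _["ops"] = ops,
                      _["gene_start"] = i,   // 0-based first aligned gene pos
                      _["gene_end"] = bi);   // 0-based past-the-end
}
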