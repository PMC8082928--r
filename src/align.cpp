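#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Banded affine-gap pairwise aligner (match/mismatch, gap_open for the first
// gap base, gap_ext for each further base; all penalties negative).
//
// Modes:
//   "global"   - both sequences consumed end to end
//   "endsfree" - overlap alignment: leading/trailing overhangs of either
//                sequence are free (truncated consensus segments)
//   "fit"      - all of b aligned, a's ends free (b placed inside a)
//   "local"    - Smith-Waterman
//
// The band is centred on the length-proportional diagonal with half-width
// w = max(min_band, ceil(band_frac * max(na, nb))); band_frac >= 1 in effect
// disables banding.
//
// Returns 0-based half-open aligned intervals on both sequences plus
// run-length encoded ops (0 = M aligned pair, 1 = I consumes b only,
// 2 = D consumes a only), the raw score, match count and alignment length.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(std::string a, std::string b,
               int match = 1, int mismatch = -2,
               int gap_open = -2, int gap_ext = -1,
               double band_frac = 0.2, int min_band = 50,
               std::string mode = "global") {
  const int na = (int)a.size(), nb = (int)b.size();
  const bool local  = (mode == "local");
  const bool free_a = (mode == "endsfree" || mode == "fit");
  const bool free_b = (mode == "endsfree");

  if (na == 0 || nb == 0) {
    IntegerVector ops, lens;
    int sc = 0;
    if (mode == "global") {
      if (na > 0) { ops.push_back(2); lens.push_back(na); sc = gap_open + (na - 1) * gap_ext; }
      if (nb > 0) { ops.push_back(1); lens.push_back(nb); sc = gap_open + (nb - 1) * gap_ext; }
    }
    return List::create(_["score"] = sc, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["ops"] = ops, _["lens"] = lens,
                        _["nmatch"] = 0, _["aln_len"] = 0);
  }

  const int w = std::max(min_band, (int)std::ceil(band_frac * std::max(na, nb)));

  std::vector<int> jlo(na + 1), jhi(na + 1);
  for (int i = 0; i <= na; ++i) {
    int c = (int)std::llround((double)i * nb / na);
    jlo[i] = std::max(0, c - w);
    jhi[i] = std::min(nb, c + w);
  }

  // rolling full-width score rows; banded traceback bytes per row
  std::vector<int> Mp(nb + 1, NEG), Xp(nb + 1, NEG), Yp(nb + 1, NEG);
  std::vector<int> Mc(nb + 1, NEG), Xc(nb + 1, NEG), Yc(nb + 1, NEG);

  // traceback codes -- M: 0 from M, 1 from X, 2 from Y, 3 fresh start
  //                    X: 0 open from M, 1 extend, 2 boundary start
  //                    Y: 0 open from M, 1 extend, 2 boundary start
  std::vector<std::vector<unsigned char> > tbM(na + 1), tbX(na + 1), tbY(na + 1);
  for (int i = 0; i <= na; ++i) {
    int width = jhi[i] - jlo[i] + 1;
    tbM[i].assign(width, 255); tbX[i].assign(width, 255); tbY[i].assign(width, 255);
  }

  // column-nb scores per row, for free trailing a / local bookkeeping
  std::vector<int> colM(na + 1, NEG), colX(na + 1, NEG), colY(na + 1, NEG);

  // row 0
  for (int j = jlo[0]; j <= jhi[0]; ++j) {
    if (j == 0) { Mp[0] = 0; tbM[0][0] = 3; }
    else if (free_b || local) { Yp[j] = 0; tbY[0][j - jlo[0]] = 2; }
    else {
      Yp[j] = gap_open + (j - 1) * gap_ext;
      tbY[0][j - jlo[0]] = (j == 1) ? 0 : 1;
    }
    if (local && j > 0) { Mp[j] = NEG; }
  }
  if (jhi[0] == nb) { colM[0] = Mp[nb]; colX[0] = Xp[nb]; colY[0] = Yp[nb]; }

  int best = NEG, bi = na, bj = nb, bs = 0;
  if (local) { best = 0; bi = 0; bj = 0; bs = 0; }

  for (int i = 1; i <= na; ++i) {
    const int lo = jlo[i], hi = jhi[i];
    for (int j = std::max(0, lo - 1); j <= hi; ++j) {
      Mc[j] = Xc[j] = Yc[j] = NEG;
      if (j < std::max(0, jlo[i - 1] - 1) || j > jhi[i - 1]) {
        Mp[j] = Xp[j] = Yp[j] = NEG;  // stale cells from older rows
      }
    }
    const char ai = a[i - 1];
    for (int j = lo; j <= hi; ++j) {
      const int off = j - lo;
      { // X: consume a (gap in b)
        int fromM = (Mp[j] > NEG) ? Mp[j] + gap_open : NEG;
        int fromX = (Xp[j] > NEG) ? Xp[j] + gap_ext : NEG;
        int v; unsigned char t;
        if (fromM >= fromX) { v = fromM; t = 0; } else { v = fromX; t = 1; }
        if (j == 0 && free_a && 0 >= v) { v = 0; t = 2; }
        Xc[j] = v; tbX[i][off] = t;
      }
      if (j >= 1) { // Y: consume b (gap in a)
        int fromM = (Mc[j - 1] > NEG) ? Mc[j - 1] + gap_open : NEG;
        int fromY = (Yc[j - 1] > NEG) ? Yc[j - 1] + gap_ext : NEG;
        int v; unsigned char t;
        if (fromM >= fromY) { v = fromM; t = 0; } else { v = fromY; t = 1; }
        Yc[j] = v; tbY[i][off] = t;
      }
      if (j >= 1) { // M: diagonal
        const int s = (ai == b[j - 1]) ? match : mismatch;
        int v = NEG; unsigned char t = 255;
        if (Mp[j - 1] > NEG && Mp[j - 1] + s > v) { v = Mp[j - 1] + s; t = 0; }
        if (Xp[j - 1] > NEG && Xp[j - 1] + s > v) { v = Xp[j - 1] + s; t = 1; }
        if (Yp[j - 1] > NEG && Yp[j - 1] + s > v) { v = Yp[j - 1] + s; t = 2; }
        if (local && 0 > v) { v = 0; t = 3; }
        Mc[j] = v; tbM[i][off] = t;
        if (local && v > best) { best = v; bi = i; bj = j; bs = 0; }
      }
    }
    if (hi == nb) { colM[i] = Mc[nb]; colX[i] = Xc[nb]; colY[i] = Yc[nb]; }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  // Mp/Xp/Yp now hold row na

  if (!local) {
    best = NEG; bi = na; bj = nb; bs = 0;
    auto consider = [&](int i, int j, int v, int s) {
      if (v > best) { best = v; bi = i; bj = j; bs = s; }
    };
    consider(na, nb, Mp[nb], 0); consider(na, nb, Xp[nb], 1); consider(na, nb, Yp[nb], 2);
    if (free_b) {
      for (int j = jlo[na]; j <= jhi[na]; ++j) consider(na, j, Mp[j], 0);
    }
    if (free_a) {
      for (int i = 0; i <= na; ++i) {
        consider(i, nb, colM[i], 0);
        consider(i, nb, colY[i], 2);
      }
    }
  }

  // traceback
  std::vector<int> ops, lens;
  int nmatch = 0, alnlen = 0;
  int i = bi, j = bj, s = bs;
  auto push_op = [&](int op) {
    if (!ops.empty() && ops.back() == op) lens.back()++;
    else { ops.push_back(op); lens.push_back(1); }
    alnlen++;
  };
  while (true) {
    if (i < 0 || j < 0) break;
    if (j < jlo[i] || j > jhi[i]) break;  // defensive: fell off the band
    if (s == 0) {
      unsigned char t = tbM[i][j - jlo[i]];
      if (t == 3 || t == 255) break;
      if (a[i - 1] == b[j - 1]) nmatch++;
      push_op(0);
      --i; --j;
      s = (t == 0) ? 0 : (t == 1 ? 1 : 2);
    } else if (s == 1) {
      unsigned char t = tbX[i][j - jlo[i]];
      if (t == 2 || t == 255) break;
      push_op(2);
      --i;
      s = (t == 0) ? 0 : 1;
    } else {
      unsigned char t = tbY[i][j - jlo[i]];
      if (t == 2 || t == 255) break;
      push_op(1);
      --j;
      s = (t == 0) ? 0 : 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(lens.begin(), lens.end());

  return List::create(_["score"] = best,
                      _["a_start"] = std::max(i, 0), _["a_end"] = bi,
                      _["b_start"] = std::max(j, 0), _["b_end"] = bj,
                      _["ops"] = wrap(ops), _["lens"] = wrap(lens),
                      _["nmatch"] = nmatch, _["aln_len"] = alnlen);
}
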