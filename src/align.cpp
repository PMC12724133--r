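#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Gotoh global alignment with affine gaps.
// A gap run of length L costs gap_open + (L-1) * gap_extend.
// Three states per cell: M (match/mismatch), X (gap in ref, consumes query),
// Y (gap in query, consumes ref). Ties are broken by a fixed source
// preference M > X > Y so the traceback is deterministic.
//
// Scores are computed in integer half-units (all inputs must be multiples of
// 0.5, which covers integer matrices such as BLOSUM62 and common DNA scoring
// schemes); the returned score is on the original scale.
//
// With free_end_gaps, leading/trailing gap runs in either sequence are free:
// row/column 0 of the gap states start at 0 and the terminal cell is the best
// cell on the last row or column (scanned in a fixed order), with the
// remaining tail emitted as unpenalised gap columns.

typedef int32_t sc_t;
static const sc_t NEG_INF = INT32_MIN / 4;

static inline sc_t half_units(double x) {
  double v = 2.0 * x;
  double r = std::nearbyint(v);
  if (std::fabs(v - r) > 1e-9)
    stop("alignment scores must be multiples of 0.5 (got %f)", x);
  return (sc_t) r;
}

static inline int pick3(sc_t m, sc_t x, sc_t y, sc_t &best) {
  best = m; int s = 0;              // preference M > X > Y on exact ties
  if (x > best) { best = x; s = 1; }
  if (y > best) { best = y; s = 2; }
  return s;
}

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string q, std::string r, NumericMatrix submat,
                     double gap_open, double gap_extend, bool free_end_gaps) {
  const int n = (int) q.size(), m = (int) r.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const sc_t open = half_units(gap_open), ext = half_units(gap_extend);

  // substitution lookup by character code, in half-units
  std::vector<sc_t> S(128 * 128, NEG_INF);
  {
    List dn = submat.attr("dimnames");
    CharacterVector rn = dn[0], cn = dn[1];
    for (int i = 0; i < submat.nrow(); ++i) {
      char a = CHAR(STRING_ELT(rn, i))[0];
      for (int j = 0; j < submat.ncol(); ++j) {
        char b = CHAR(STRING_ELT(cn, j))[0];
        S[(unsigned char)a * 128 + (unsigned char)b] = half_units(submat(i, j));
      }
    }
  }
  for (char c : r) if (S[(unsigned char)c * 128 + (unsigned char)c] <= NEG_INF / 2)
    stop("character '%c' not in substitution matrix", c);
  for (char c : q) if (S[(unsigned char)c * 128 + (unsigned char)c] <= NEG_INF / 2)
    stop("character '%c' not in substitution matrix", c);

  // traceback byte layout: bits 0-1 source of M, 2-3 of X, 4-5 of Y
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  std::vector<sc_t> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<sc_t> colM(n + 1), colX(n + 1), colY(n + 1); // last-column values

  Mp[0] = 0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = free_end_gaps ? 0 : -(open + (j - 1) * ext);
    tb[(size_t)0 * (m + 1) + j] = (uint8_t)(((j == 1 ? 0 : 2)) << 4);
  }
  colM[0] = Mp[m]; colX[0] = Xp[m]; colY[0] = Yp[m];

  for (int i = 1; i <= n; ++i) {
    // row i computed in place over row i-1; diagonal values carried in
    // registers (dM/dX/dY hold the previous row's column j-1)
    sc_t dM = Mp[0], dX = Xp[0], dY = Yp[0];
    sc_t mc = NEG_INF, yc = NEG_INF;
    sc_t xc = free_end_gaps ? 0 : -(open + (i - 1) * ext);
    Mp[0] = mc; Xp[0] = xc; Yp[0] = yc;
    tb[(size_t)i * (m + 1) + 0] = (uint8_t)((i == 1 ? 0 : 1) << 2);
    const sc_t *Srow = &S[(unsigned char)q[i - 1] * 128];
    uint8_t *tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      const sc_t uM = Mp[j], uX = Xp[j], uY = Yp[j]; // row i-1, col j
      sc_t best;
      const int sm = pick3(dM, dX, dY, best);
      const sc_t Mv = best + Srow[(unsigned char)r[j - 1]];
      const int sx = pick3(uM - open, uX - ext, uY - open, best);
      const sc_t Xv = best;
      const int sy = pick3(mc - open, xc - open, yc - ext, best);
      const sc_t Yv = best;
      mc = Mv; xc = Xv; yc = Yv;
      dM = uM; dX = uX; dY = uY;
      Mp[j] = Mv; Xp[j] = Xv; Yp[j] = Yv;
      tbrow[j] = (uint8_t)(sm | (sx << 2) | (sy << 4));
    }
    colM[i] = Mp[m]; colX[i] = Xp[m]; colY[i] = Yp[m];
  }
  // Mp/Xp/Yp now hold row n

  int ei = n, ej = m, estate;
  sc_t score;
  {
    sc_t best;
    estate = pick3(colM[n], colX[n], colY[n], best);
    score = best;
  }
  if (free_end_gaps) {
    // include row/column 0: an end cell there means one sequence is entirely
    // a (free) leading gap and the other entirely a (free) trailing gap
    for (int i = n; i >= 0; --i) {
      sc_t best; int s = pick3(colM[i], colX[i], colY[i], best);
      if (best > score) { score = best; ei = i; ej = m; estate = s; }
    }
    sc_t col0M = (n == 0) ? 0 : NEG_INF;
    sc_t col0X = free_end_gaps ? 0 : NEG_INF;
    for (int j = m; j >= 1; --j) {
      sc_t best; int s = pick3(Mp[j], Xp[j], Yp[j], best);
      if (best > score) { score = best; ei = n; ej = j; estate = s; }
    }
    {
      sc_t best; int s = pick3(col0M, col0X, NEG_INF, best);
      if (best > score) { score = best; ei = n; ej = 0; estate = s; }
    }
  }

  // traceback: D = diagonal, U = consume query (gap in ref), L = consume ref
  std::string moves;
  int i = ei, j = ej, st = estate;
  while (i > 0 || j > 0) {
    uint8_t b = tb[(size_t)i * (m + 1) + j];
    if (st == 0) { moves.push_back('D'); st = b & 3;        --i; --j; }
    else if (st == 1) { moves.push_back('U'); st = (b >> 2) & 3; --i; }
    else { moves.push_back('L'); st = (b >> 4) & 3; --j; }
    if (i == 0 && j > 0) st = 2;
    else if (j == 0 && i > 0) st = 1;
  }
  std::reverse(moves.begin(), moves.end());
  for (int k = ei; k < n; ++k) moves.push_back('U');
  for (int k = ej; k < m; ++k) moves.push_back('L');

  const int L = (int) moves.size();
  IntegerVector qpos(L), rpos(L);
  int qi = 0, rj = 0;
  for (int k = 0; k < L; ++k) {
    char mv = moves[k];
    if (mv == 'D') { qpos[k] = ++qi; rpos[k] = ++rj; }
    else if (mv == 'U') { qpos[k] = ++qi; rpos[k] = NA_INTEGER; }
    else { qpos[k] = NA_INTEGER; rpos[k] = ++rj; }
  }
  return List::create(_["score"] = score / 2.0, _["qpos"] = qpos,
                      _["rpos"] = rpos, _["moves"] = moves);
}
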