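// Smith-Waterman local alignment with affine gaps (Gotoh recurrences).
//
// Gap convention: a gap run of length L costs open + (L-1)*extend, i.e. the
// first gap column pays the full `open` penalty and each further column pays
// `extend`.  Scores may be fractional (extend defaults to 0.5 upstream).
//
// Tie-breaks (fixed for determinism):
//   * cell choice: diagonal > gap-in-reference (consume query, move up)
//     > gap-in-query (consume reference, move left) > restart at 0;
//   * gap recurrences: opening from H preferred over extending on ties;
//   * best cell over the matrix: highest score, then smallest reference end
//     position, then smallest query end position.
//
// Two entry points:
//   cpp_sw_prefix_scan: linear-memory pass returning, for every query prefix
//     [1..L], the score / match count / interval of the optimal local
//     alignment of that prefix against the reference.  Row L of the output
//     is bit-identical to what a standalone run on the prefix would produce,
//     because the DP rows of a prefix are a prefix of the full DP.
//   cpp_sw_traceback: full alignment of the whole query with aligned strings
//     (pointer matrices, O(n*m) bytes).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const double NEG_INF = -1e30;

struct Cell {
  double v;   // score
  int m;      // matches on the path
  int qs;     // query start (1-based); 0 marks the empty alignment
  int rs;     // reference start
};

static inline Cell empty_cell() { Cell c; c.v = 0.0; c.m = 0; c.qs = 0; c.rs = 0; return c; }
static inline Cell invalid_cell() { Cell c; c.v = NEG_INF; c.m = 0; c.qs = 0; c.rs = 0; return c; }

// [[Rcpp::export]]
NumericMatrix cpp_sw_prefix_scan(IntegerVector q, IntegerVector r,
                                 NumericMatrix lookup, double open, double ext) {
  const int n = q.size(), m = r.size();
  const int nsym = lookup.nrow();
  const double *lk = REAL(lookup);
  const int *qc = INTEGER(q);
  const int *rc = INTEGER(r);

  std::vector<Cell> prevH(m + 1, empty_cell()), curH(m + 1, empty_cell());
  std::vector<Cell> prevF(m + 1, invalid_cell()), curF(m + 1, invalid_cell());

  NumericMatrix out(n, 6);  // score, matches, qs, qe, rs, re
  Cell best = empty_cell();
  int bi = 0, bj = 0;
  double bscore = 0.0;

  for (int i = 1; i <= n; ++i) {
    const double *Lrow = lk + qc[i - 1];
    curH[0] = empty_cell();
    curF[0] = invalid_cell();
    Cell E = invalid_cell();
    for (int j = 1; j <= m; ++j) {
      const double s = Lrow[(size_t)nsym * rc[j - 1]];

      // F: gap in reference (vertical), consumes q[i]
      {
        const double fopen = prevH[j].v - open;
        const double fext  = prevF[j].v - ext;
        if (fopen >= fext) {
          curF[j].v = fopen; curF[j].m = prevH[j].m;
          curF[j].qs = prevH[j].qs; curF[j].rs = prevH[j].rs;
        } else {
          curF[j].v = fext; curF[j].m = prevF[j].m;
          curF[j].qs = prevF[j].qs; curF[j].rs = prevF[j].rs;
        }
      }
      // E: gap in query (horizontal), consumes r[j]
      {
        const double eopen = curH[j - 1].v - open;
        const double eext  = E.v - ext;
        if (eopen >= eext) {
          E.v = eopen; E.m = curH[j - 1].m;
          E.qs = curH[j - 1].qs; E.rs = curH[j - 1].rs;
        } else {
          E.v = eext;  // m, qs, rs unchanged (extend)
        }
      }
      // H
      const Cell &dp = prevH[j - 1];
      const double dval = dp.v + s;
      double hv = dval;
      if (curF[j].v > hv) hv = curF[j].v;
      if (E.v > hv) hv = E.v;
      if (hv <= 0.0) {
        curH[j] = empty_cell();
      } else if (dval == hv) {
        Cell hd;
        hd.v = dval;
        hd.m = dp.m + (qc[i - 1] == rc[j - 1] ? 1 : 0);
        if (dp.qs == 0) { hd.qs = i; hd.rs = j; } else { hd.qs = dp.qs; hd.rs = dp.rs; }
        curH[j] = hd;
      } else if (curF[j].v == hv) {
        curH[j] = curF[j];
      } else {
        curH[j] = E;
      }
      // running best: score desc, then (re, qe) lexicographically ascending
      const double v = curH[j].v;
      if (v > bscore ||
          (v == bscore && v > 0.0 && (j < bj || (j == bj && i < bi)))) {
        bscore = v; best = curH[j]; bi = i; bj = j;
      }
    }
    out(i - 1, 0) = bscore;
    out(i - 1, 1) = best.m;
    out(i - 1, 2) = best.qs;
    out(i - 1, 3) = bscore > 0.0 ? bi : 0;
    out(i - 1, 4) = best.rs;
    out(i - 1, 5) = bscore > 0.0 ? bj : 0;
    std::swap(prevH, curH);
    std::swap(prevF, curF);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sw_traceback(IntegerVector q, IntegerVector r,
                      NumericMatrix lookup, double open, double ext,
                      std::string qstr, std::string rstr) {
  const int n = q.size(), m = r.size();
  const int nsym = lookup.nrow();
  const double *lk = REAL(lookup);
  const int *qc = INTEGER(q);
  const int *rc = INTEGER(r);

  if ((double)n * (double)m > 6e8)
    stop("alignment matrix too large for traceback (%d x %d)", n, m);

  // pointer matrices, row-major (i-1)*m + (j-1)
  std::vector<uint8_t> ptrH((size_t)n * m, 0);  // 0 stop, 1 diag, 2 up(F), 3 left(E)
  std::vector<uint8_t> ptrF((size_t)n * m, 0);  // 1 open, 0 extend
  std::vector<uint8_t> ptrE((size_t)n * m, 0);

  std::vector<double> prevH(m + 1, 0.0), curH(m + 1, 0.0);
  std::vector<double> prevF(m + 1, NEG_INF), curF(m + 1, NEG_INF);

  double bscore = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    const double *Lrow = lk + qc[i - 1];
    curH[0] = 0.0;
    curF[0] = NEG_INF;
    double E = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      const size_t k = (size_t)(i - 1) * m + (j - 1);
      const double s = Lrow[(size_t)nsym * rc[j - 1]];

      const double fopen = prevH[j] - open;
      const double fext  = prevF[j] - ext;
      if (fopen >= fext) { curF[j] = fopen; ptrF[k] = 1; }
      else               { curF[j] = fext;  ptrF[k] = 0; }

      const double eopen = curH[j - 1] - open;
      const double eext  = E - ext;
      if (eopen >= eext) { E = eopen; ptrE[k] = 1; }
      else               { E = eext;  ptrE[k] = 0; }

      const double dval = prevH[j - 1] + s;
      double hv = dval;
      if (curF[j] > hv) hv = curF[j];
      if (E > hv) hv = E;
      if (hv <= 0.0)            { curH[j] = 0.0; ptrH[k] = 0; }
      else if (dval == hv)      { curH[j] = dval; ptrH[k] = 1; }
      else if (curF[j] == hv)   { curH[j] = curF[j]; ptrH[k] = 2; }
      else                      { curH[j] = E; ptrH[k] = 3; }

      if (curH[j] > bscore ||
          (curH[j] == bscore && curH[j] > 0.0 && (j < bj || (j == bj && i < bi)))) {
        bscore = curH[j]; bi = i; bj = j;
      }
    }
    std::swap(prevH, curH);
    std::swap(prevF, curF);
  }

  if (bscore <= 0.0) {
    return List::create(_["score"] = 0.0, _["matches"] = (int)0,
                        _["qs"] = NA_INTEGER, _["qe"] = NA_INTEGER,
                        _["rs"] = NA_INTEGER, _["re"] = NA_INTEGER,
                        _["alignedQuery"] = "", _["alignedRef"] = "");
  }

  std::string aq, ar;
  int i = bi, j = bj, matches = 0;
  int state = 0;  // 0 = H, 2 = F, 3 = E
  while (i >= 1 && j >= 1) {
    const size_t k = (size_t)(i - 1) * m + (j - 1);
    if (state == 0) {
      const uint8_t p = ptrH[k];
      if (p == 0) break;
      if (p == 1) {
        aq.push_back(qstr[i - 1]);
        ar.push_back(rstr[j - 1]);
        if (qc[i - 1] == rc[j - 1]) ++matches;
        --i; --j;
      } else {
        state = (int)p;  // 2 -> F, 3 -> E
      }
    } else if (state == 2) {  // gap in reference, consume query
      aq.push_back(qstr[i - 1]);
      ar.push_back('-');
      state = ptrF[k] == 1 ? 0 : 2;
      --i;
    } else {  // gap in query, consume reference
      aq.push_back('-');
      ar.push_back(rstr[j - 1]);
      state = ptrE[k] == 1 ? 0 : 3;
      --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());

  return List::create(_["score"] = bscore, _["matches"] = matches,
                      _["qs"] = i + 1, _["qe"] = bi,
                      _["rs"] = j + 1, _["re"] = bj,
                      _["alignedQuery"] = aq, _["alignedRef"] = ar);
}
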