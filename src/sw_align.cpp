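#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-state DP).
// A gap of length L costs gap_open + L * gap_extend. Any column involving
// N scores as a mismatch and never counts as an identity. The optimum
// starts and ends in the match state (terminal gaps never help a local
// alignment with positive gap costs). Ties in the DP maximum are broken
// toward the first cell reached in row-major order, giving a
// deterministic traceback.
//
// Traceback is packed into one byte per cell:
//   bits 0-1: M source   (0 local start, 1 M, 2 Ix, 3 Iy; diagonal move)
//   bits 2-3: Ix source  (1 open from M, 2 extend, 3 open from Iy)
//   bits 4-5: Iy source  (1 open from M, 2 extend, 3 open from Ix)
//
// Returns score, 0-based half-open query/target intervals, the number of
// identical aligned columns and the total number of aligned columns.
// [[Rcpp::export]]
List cpp_sw_align(const std::string& q, const std::string& t,
                  int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int) q.size(), m = (int) t.size();
  const int NEG = -1000000000;
  const int go = gap_open + gap_ext;  // cost of the first gapped base
  const int ge = gap_ext;

  std::vector<int> Mp(m + 1, 0), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<int> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    int *Mcur = Mc.data(), *Xcur = Xc.data(), *Ycur = Yc.data();
    const int *Mpr = Mp.data(), *Xpr = Xp.data(), *Ypr = Yp.data();
    unsigned char *tbr = tb.data() + (size_t) i * (m + 1);
    Mcur[0] = 0; Xcur[0] = NEG; Ycur[0] = NEG;
    int diagM = 0, diagX = NEG, diagY = NEG;  // previous row, column j-1
    for (int j = 1; j <= m; ++j) {
      unsigned char cell;

      // Ix: consume q[i-1] (vertical)
      const int upM = Mpr[j], upX = Xpr[j], upY = Ypr[j];
      int x_open = (upM >= upY ? upM : upY) - go;
      int x_ext  = upX - ge;
      int xval; unsigned char xdir;
      if (x_open >= x_ext) { xval = x_open; xdir = (upM >= upY) ? 1 : 3; }
      else                 { xval = x_ext;  xdir = 2; }
      Xcur[j] = xval;
      cell = (unsigned char)(xdir << 2);

      // Iy: consume t[j-1] (horizontal)
      const int lfM = Mcur[j - 1], lfX = Xcur[j - 1], lfY = Ycur[j - 1];
      int y_open = (lfM >= lfX ? lfM : lfX) - go;
      int y_ext  = lfY - ge;
      int yval; unsigned char ydir;
      if (y_open >= y_ext) { yval = y_open; ydir = (lfM >= lfX) ? 1 : 3; }
      else                 { yval = y_ext;  ydir = 2; }
      Ycur[j] = yval;
      cell |= (unsigned char)(ydir << 4);

      // M: diagonal
      const char tc = t[j - 1];
      const int s = (qc == tc && qc != 'N') ? match : mismatch;
      int dbest = diagM; unsigned char mdir = 1;
      if (diagX > dbest) { dbest = diagX; mdir = 2; }
      if (diagY > dbest) { dbest = diagY; mdir = 3; }
      int val = dbest + s;
      if (val <= 0) { val = 0; mdir = 0; }
      Mcur[j] = val;
      tbr[j] = cell | mdir;
      if (val > best) { best = val; bi = i; bj = j; }

      diagM = upM; diagX = upX; diagY = upY;
    }
    std::swap(Mc, Mp); std::swap(Xc, Xp); std::swap(Yc, Yp);
  }

  if (best <= 0)
    return List::create(_["score"] = 0, _["qs"] = 0, _["qe"] = 0,
                        _["ts"] = 0, _["te"] = 0,
                        _["n_match"] = 0, _["n_cols"] = 0);

  // Traceback from (bi, bj) in state M.
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  int n_match = 0, n_cols = 0;
  for (;;) {
    const unsigned char cell = tb[(size_t) i * (m + 1) + j];
    if (state == 0) {
      const unsigned char d = cell & 3;
      ++n_cols;
      if (q[i - 1] == t[j - 1] && q[i - 1] != 'N') ++n_match;
      --i; --j;
      if (d == 1) {
        // stop when the diagonal predecessor is a fresh local start
        if (i == 0 || j == 0 ||
            (tb[(size_t) i * (m + 1) + j] & 3) == 0) break;
      } else if (d == 2) state = 1;
      else if (d == 3) state = 2;
      else Rcpp::stop("corrupt traceback");
    } else if (state == 1) {
      const unsigned char d = (cell >> 2) & 3;
      ++n_cols; --i;
      state = (d == 2) ? 1 : (d == 1 ? 0 : 2);
    } else {
      const unsigned char d = (cell >> 4) & 3;
      ++n_cols; --j;
      state = (d == 2) ? 2 : (d == 1 ? 0 : 1);
    }
  }

  return List::create(_["score"] = best,
                      _["qs"] = i, _["qe"] = bi,
                      _["ts"] = j, _["te"] = bj,
                      _["n_match"] = n_match, _["n_cols"] = n_cols);
}
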