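// Needleman-Wunsch global alignment with affine gaps (Gotoh), replicating
// the EMBOSS needle/needleall cost convention: a gap of length L costs
// gap_open + L * gap_extend, and end gaps are free by default.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// traceback states
enum State { ST_M = 0, ST_X = 1, ST_Y = 2 }; // X: gap in b (consumes a), Y: gap in a (consumes b)

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(IntegerVector a, IntegerVector b, NumericMatrix score,
              double gap_open, double gap_extend, bool free_end_gaps) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend; // cost of first gap residue
  const double ge = gap_extend;

  // DP matrices, (n+1) x (m+1), column-major vectors
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: predecessor state for each state at each cell
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((n + 1) * (m + 1), -1);
  #define IX(i, j) ((i) + (std::size_t)(n + 1) * (j))

  M[IX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IX(i, 0)] = free_end_gaps ? 0.0 : -(go + ge * (i - 1));
    tbX[IX(i, 0)] = ST_X;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IX(0, j)] = free_end_gaps ? 0.0 : -(go + ge * (j - 1));
    tbY[IX(0, j)] = ST_Y;
  }

  for (int j = 1; j <= m; ++j) {
    for (int i = 1; i <= n; ++i) {
      const double s = score(a[i - 1], b[j - 1]);
      // M: diagonal from any state; tie-break M > X > Y
      {
        double vm = M[IX(i - 1, j - 1)], vx = X[IX(i - 1, j - 1)], vy = Y[IX(i - 1, j - 1)];
        double best = vm; signed char st = ST_M;
        if (vx > best) { best = vx; st = ST_X; }
        if (vy > best) { best = vy; st = ST_Y; }
        M[IX(i, j)] = best + s;
        tbM[IX(i, j)] = st;
      }
      // X: gap in b, consume a[i-1]; open from M or Y, extend from X
      {
        double vo = M[IX(i - 1, j)] - go;
        double vx = X[IX(i - 1, j)] - ge;
        double vy = Y[IX(i - 1, j)] - go;
        double best = vo; signed char st = ST_M;
        if (vx > best) { best = vx; st = ST_X; }
        if (vy > best) { best = vy; st = ST_Y; }
        X[IX(i, j)] = best;
        tbX[IX(i, j)] = st;
      }
      // Y: gap in a, consume b[j-1]
      {
        double vo = M[IX(i, j - 1)] - go;
        double vx = X[IX(i, j - 1)] - go;
        double vy = Y[IX(i, j - 1)] - ge;
        double best = vo; signed char st = ST_M;
        if (vx > best) { best = vx; st = ST_X; }
        if (vy > best) { best = vy; st = ST_Y; }
        Y[IX(i, j)] = best;
        tbY[IX(i, j)] = st;
      }
    }
  }

  // termination
  int ei = n, ej = m;
  signed char est;
  double best_score;
  {
    double vm = M[IX(n, m)], vx = X[IX(n, m)], vy = Y[IX(n, m)];
    best_score = vm; est = ST_M;
    if (vx > best_score) { best_score = vx; est = ST_X; }
    if (vy > best_score) { best_score = vy; est = ST_Y; }
  }
  if (free_end_gaps) {
    // trailing end gaps cost 0: best cell over last row / last column,
    // preferring completion nearest the corner (deterministic)
    for (int i = n; i >= 0; --i) {
      double vm = M[IX(i, m)], vx = X[IX(i, m)], vy = Y[IX(i, m)];
      double v = vm; signed char st = ST_M;
      if (vx > v) { v = vx; st = ST_X; }
      if (vy > v) { v = vy; st = ST_Y; }
      if (v > best_score) { best_score = v; ei = i; ej = m; est = st; }
    }
    for (int j = m; j >= 0; --j) {
      double vm = M[IX(n, j)], vx = X[IX(n, j)], vy = Y[IX(n, j)];
      double v = vm; signed char st = ST_M;
      if (vx > v) { v = vx; st = ST_X; }
      if (vy > v) { v = vy; st = ST_Y; }
      if (v > best_score) { best_score = v; ei = n; ej = j; est = st; }
    }
  }

  // traceback, building index vectors (0 = gap)
  std::vector<int> ta, tb;
  ta.reserve(n + m); tb.reserve(n + m);
  // trailing free end gaps
  for (int i = n; i > ei; --i) { ta.push_back(a[i - 1] + 1); tb.push_back(0); }
  for (int j = m; j > ej; --j) { ta.push_back(0); tb.push_back(b[j - 1] + 1); }
  int i = ei, j = ej;
  signed char st = est;
  while (i > 0 || j > 0) {
    if (st == ST_M) {
      if (i == 0 || j == 0) break; // M only holds at origin
      signed char prev = tbM[IX(i, j)];
      ta.push_back(a[i - 1] + 1); tb.push_back(b[j - 1] + 1);
      --i; --j; st = prev;
    } else if (st == ST_X) {
      signed char prev = tbX[IX(i, j)];
      ta.push_back(a[i - 1] + 1); tb.push_back(0);
      --i; st = prev;
    } else {
      signed char prev = tbY[IX(i, j)];
      ta.push_back(0); tb.push_back(b[j - 1] + 1);
      --j; st = prev;
    }
  }
  std::reverse(ta.begin(), ta.end());
  std::reverse(tb.begin(), tb.end());

  return List::create(_["score"] = best_score,
                      _["ai"] = IntegerVector(ta.begin(), ta.end()),
                      _["bi"] = IntegerVector(tb.begin(), tb.end()));
}

// Score-only variant (two-row DP), used for reciprocal-best-hit searches.
// [[Rcpp::export(name = ".nw_score")]]
double nw_score(IntegerVector a, IntegerVector b, NumericMatrix score,
                double gap_open, double gap_extend, bool free_end_gaps) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1), Mc(m + 1), Xc(m + 1), Yc(m + 1);
  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = free_end_gaps ? 0.0 : -(go + ge * (j - 1));
  }
  double best = NEG_INF;
  if (free_end_gaps) best = std::max({Mp[m], Yp[m]});
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF; Yc[0] = NEG_INF;
    Xc[0] = free_end_gaps ? 0.0 : -(go + ge * (i - 1));
    for (int j = 1; j <= m; ++j) {
      const double s = score(a[i - 1], b[j - 1]);
      Mc[j] = std::max({Mp[j - 1], Xp[j - 1], Yp[j - 1]}) + s;
      Xc[j] = std::max({Mp[j] - go, Xp[j] - ge, Yp[j] - go});
      Yc[j] = std::max({Mc[j - 1] - go, Xc[j - 1] - go, Yc[j - 1] - ge});
    }
    if (free_end_gaps) {
      double rowbest = std::max({Mc[m], Xc[m], Yc[m]});
      if (rowbest > best) best = rowbest;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  if (!free_end_gaps) return std::max({Mp[m], Xp[m], Yp[m]});
  // free trailing gaps: best over last column tracked per row above; last row
  // (i = n) is in Mp/Xp/Yp after the final swap
  for (int j = 0; j <= m; ++j) {
    double v = std::max({Mp[j], Xp[j], Yp[j]});
    if (v > best) best = v;
  }
  return best;
}
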