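// Dense two-phase primal simplex for the density-reconciliation LP.
//
// Solves  min c'x  s.t.  A x (<=,==,>=) b,  x >= 0.
// Phase 1 minimizes the sum of artificial variables; phase 2 optimizes the
// true objective with artificial columns blocked. Entering variable by
// Dantzig pricing with a permanent switch to Bland's rule after a stall,
// which guarantees termination on degenerate problems. The problems solved
// here are modest (hundreds of rows), so a dense tableau is appropriate.

#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double PIV_TOL = 1e-9;
static const double RC_TOL = 1e-9;

// [[Rcpp::export(name = ".simplexCpp")]]
List simplexCpp(NumericVector obj, NumericMatrix A, IntegerVector dir,
                NumericVector rhs, int maxIter = 0) {
  const int m = A.nrow(), n = A.ncol();
  std::vector<int> rdir(dir.begin(), dir.end()); // 0: <=, 1: ==, 2: >=
  std::vector<double> b(rhs.begin(), rhs.end());
  std::vector<double> sgn(m, 1.0);
  for (int i = 0; i < m; ++i) {
    if (b[i] < 0) { // normalize to b >= 0
      b[i] = -b[i]; sgn[i] = -1.0;
      if (rdir[i] == 0) rdir[i] = 2; else if (rdir[i] == 2) rdir[i] = 0;
    }
  }
  int nSlack = 0, nArt = 0;
  for (int i = 0; i < m; ++i) {
    if (rdir[i] == 0 || rdir[i] == 2) ++nSlack;
    if (rdir[i] == 1 || rdir[i] == 2) ++nArt;
  }
  const int N = n + nSlack + nArt;   // columns excluding rhs
  // tableau: m rows x (N+1); last column = rhs
  std::vector<std::vector<double>> T(m, std::vector<double>(N + 1, 0.0));
  std::vector<int> basis(m, -1);
  std::vector<bool> isArt(N, false);
  int sc = n, ac = n + nSlack;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T[i][j] = sgn[i] * A(i, j);
    T[i][N] = b[i];
    if (rdir[i] == 0) {                 // <= : slack, basic
      T[i][sc] = 1.0; basis[i] = sc; ++sc;
    } else if (rdir[i] == 2) {          // >= : surplus + artificial
      T[i][sc] = -1.0; ++sc;
      T[i][ac] = 1.0; isArt[ac] = true; basis[i] = ac; ++ac;
    } else {                            // == : artificial
      T[i][ac] = 1.0; isArt[ac] = true; basis[i] = ac; ++ac;
    }
  }
  // reduced-cost rows (length N+1, last entry = -objective value)
  std::vector<double> d1(N + 1, 0.0), d2(N + 1, 0.0);
  for (int j = 0; j < N; ++j) d1[j] = isArt[j] ? 1.0 : 0.0;
  for (int j = 0; j < n; ++j) d2[j] = obj[j];
  // canonicalize cost rows w.r.t. the initial basis (artificials have cost 1)
  for (int i = 0; i < m; ++i) {
    if (isArt[basis[i]])
      for (int j = 0; j <= N; ++j) d1[j] -= T[i][j];
  }
  if (maxIter <= 0) maxIter = 2000 + 200 * (m + N);

  auto pivot = [&](int pr, int pc) {
    const double pv = T[pr][pc];
    for (int j = 0; j <= N; ++j) T[pr][j] /= pv;
    for (int i = 0; i < m; ++i) {
      if (i == pr) continue;
      const double f = T[i][pc];
      if (f != 0.0) for (int j = 0; j <= N; ++j) T[i][j] -= f * T[pr][j];
    }
    for (auto *d : {&d1, &d2}) {
      const double f = (*d)[pc];
      if (f != 0.0) for (int j = 0; j <= N; ++j) (*d)[j] -= f * T[pr][j];
    }
    basis[pr] = pc;
  };

  auto runPhase = [&](std::vector<double> &d, bool blockArt) -> int {
    bool bland = false;
    int stall = 0;
    double lastObj = std::numeric_limits<double>::infinity();
    for (int it = 0; it < maxIter; ++it) {
      int pc = -1;
      double best = -RC_TOL;
      for (int j = 0; j < N; ++j) {
        if (blockArt && isArt[j]) continue;
        if (d[j] < (bland ? -RC_TOL : best)) {
          pc = j;
          if (bland) break;
          best = d[j];
        }
      }
      if (pc < 0) return 0;                      // optimal
      int pr = -1;
      double bestRatio = std::numeric_limits<double>::infinity();
      for (int i = 0; i < m; ++i) {
        if (T[i][pc] > PIV_TOL) {
          const double ratio = T[i][N] / T[i][pc];
          if (ratio < bestRatio - 1e-12 ||
              (ratio < bestRatio + 1e-12 && (pr < 0 || basis[i] < basis[pr]))) {
            bestRatio = ratio; pr = i;
          }
        }
      }
      if (pr < 0) return 1;                      // unbounded
      pivot(pr, pc);
      const double curObj = -d[N];
      if (curObj < lastObj - 1e-12) { lastObj = curObj; stall = 0; }
      else if (++stall > 50) bland = true;       // anti-cycling fallback
    }
    return 2;                                    // iteration limit
  };

  int st = runPhase(d1, false);
  double phase1 = -d1[N];
  if (st == 2) return List::create(_["status"] = "iteration_limit");
  if (phase1 > 1e-7)
    return List::create(_["status"] = "infeasible", _["phase1"] = phase1);
  // drive remaining artificials (basic at zero) out of the basis
  for (int i = 0; i < m; ++i) {
    if (isArt[basis[i]]) {
      int pc = -1;
      for (int j = 0; j < n + nSlack; ++j)
        if (std::abs(T[i][j]) > PIV_TOL) { pc = j; break; }
      if (pc >= 0) pivot(i, pc);
      // else: redundant row; artificial stays basic at value 0 and is
      // blocked from re-entering in phase 2
    }
  }
  st = runPhase(d2, true);
  if (st == 1) return List::create(_["status"] = "unbounded");
  if (st == 2) return List::create(_["status"] = "iteration_limit");

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) x[basis[i]] = T[i][N];
  double objVal = 0.0;
  for (int j = 0; j < n; ++j) objVal += obj[j] * x[j];
  return List::create(_["status"] = "optimal", _["x"] = x,
                      _["objective"] = objVal);
}
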