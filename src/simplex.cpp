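// Dense bounded-variable two-phase primal simplex.
//
// Solves:  maximize c'x  subject to  A x = b,  0 <= x <= u
// (u may be +Inf componentwise).  Variables are nonbasic at either bound;
// phase 1 drives an artificial basis to zero, phase 2 optimizes c.  Dantzig
// pricing with a switch to Bland's rule to guarantee termination on
// degenerate problems.  Intended for the small dense LPs of toy
// genome-scale models (tens of metabolites, a few hundred reactions).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double TOL = 1e-9;       // pricing / pivot tolerance
static const double FEAS_TOL = 1e-7;  // phase-1 infeasibility threshold

namespace {

struct Tableau {
  int m, n;                 // rows, structural columns
  int N;                    // total columns (structural + artificial)
  std::vector<double> T;    // m x N, column-major
  std::vector<double> xB;   // basic values
  std::vector<int> basis;   // column index basic in each row
  std::vector<char> at_up;  // nonbasic-at-upper flag per column
  std::vector<double> u;    // upper bounds per column (inf allowed)

  double &at(int i, int j) { return T[static_cast<size_t>(j) * m + i]; }
};

// one simplex phase; obj has length N; barred columns never enter.
// returns 0 optimal, 2 unbounded, 3 iteration limit.
int run_phase(Tableau &tb, const std::vector<double> &obj,
              const std::vector<char> &barred, int maxit, int bland_after) {
  const int m = tb.m, N = tb.N;
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> d(N);

  for (int iter = 0; iter < maxit; ++iter) {
    bool bland = iter >= bland_after;

    // reduced costs d = obj - T' * obj[basis]
    std::vector<double> y(m);
    for (int i = 0; i < m; ++i) y[i] = obj[tb.basis[i]];
    std::vector<char> is_basic(N, 0);
    for (int i = 0; i < m; ++i) is_basic[tb.basis[i]] = 1;
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      const double *col = &tb.T[static_cast<size_t>(j) * m];
      for (int i = 0; i < m; ++i) s += y[i] * col[i];
      d[j] = obj[j] - s;
    }

    // entering column
    int enter = -1;
    double best = TOL;
    for (int j = 0; j < N; ++j) {
      if (is_basic[j] || barred[j]) continue;
      double dj = tb.at_up[j] ? -d[j] : d[j];  // improvement rate
      if (dj > TOL) {
        if (bland) { enter = j; break; }
        if (dj > best) { best = dj; enter = j; }
      }
    }
    if (enter < 0) return 0;  // optimal

    double s = tb.at_up[enter] ? -1.0 : 1.0;
    const double *a = &tb.T[static_cast<size_t>(enter) * m];

    // ratio test
    double tmax = tb.u[enter];  // bound-to-bound flip distance
    int leave = -1;
    char leave_up = 0;
    for (int i = 0; i < m; ++i) {
      double w = s * a[i];  // rate of decrease of xB[i]
      double ti;
      char to_up;
      if (w > TOL) {
        ti = tb.xB[i] / w;
        to_up = 0;
      } else if (w < -TOL) {
        double ub = tb.u[tb.basis[i]];
        if (!std::isfinite(ub)) continue;
        ti = (ub - tb.xB[i]) / (-w);
        to_up = 1;
      } else {
        continue;
      }
      if (ti < 0) ti = 0;
      bool take = false;
      if (ti < tmax - 1e-10) {
        take = true;
      } else if (ti < tmax + 1e-10 && leave >= 0) {
        // tie-break: Bland -> lowest basis index; else largest pivot
        take = bland ? (tb.basis[i] < tb.basis[leave])
                     : (std::fabs(a[i]) > std::fabs(a[leave]));
      }
      if (take) { tmax = ti; leave = i; leave_up = to_up; }
    }

    if (!std::isfinite(tmax)) return 2;  // unbounded

    if (leave < 0) {
      // entering variable flips to its other bound, basis unchanged
      for (int i = 0; i < m; ++i) tb.xB[i] -= s * tmax * a[i];
      tb.at_up[enter] = !tb.at_up[enter];
    } else {
      double enter_val = tb.at_up[enter] ? tb.u[enter] - tmax : tmax;
      for (int i = 0; i < m; ++i)
        if (i != leave) tb.xB[i] -= s * tmax * a[i];
      int lv = tb.basis[leave];
      tb.at_up[lv] = leave_up;
      tb.at_up[enter] = 0;
      tb.basis[leave] = enter;
      tb.xB[leave] = enter_val;

      // pivot row operations
      double piv = a[leave];
      double *prow_base = &tb.T[0];
      // scale pivot row
      for (int j = 0; j < N; ++j)
        tb.at(leave, j) /= piv;
      for (int i = 0; i < m; ++i) {
        if (i == leave) continue;
        double f = tb.at(i, enter);
        if (std::fabs(f) < 1e-13) continue;
        for (int j = 0; j < N; ++j)
          tb.at(i, j) -= f * tb.at(leave, j);
      }
      (void)prow_base;
    }
    // clamp round-off
    for (int i = 0; i < m; ++i) {
      if (tb.xB[i] < 0 && tb.xB[i] > -1e-9) tb.xB[i] = 0;
      double ub = tb.u[tb.basis[i]];
      if (std::isfinite(ub) && tb.xB[i] > ub && tb.xB[i] < ub + 1e-9)
        tb.xB[i] = ub;
    }
  }
  return 3;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_box")]]
List simplex_box(NumericMatrix A, NumericVector b, NumericVector c,
                 NumericVector upper, int maxit = 50000) {
  const int m = A.nrow(), n = A.ncol();
  const double inf = std::numeric_limits<double>::infinity();

  Tableau tb;
  tb.m = m;
  tb.n = n;
  tb.N = n + m;
  tb.T.assign(static_cast<size_t>(tb.N) * m, 0.0);
  tb.u.assign(tb.N, inf);
  tb.at_up.assign(tb.N, 0);
  tb.basis.resize(m);
  tb.xB.resize(m);

  // rows flipped so that b >= 0; artificial identity basis
  std::vector<double> sign(m, 1.0);
  for (int i = 0; i < m; ++i)
    if (b[i] < 0) sign[i] = -1.0;
  for (int j = 0; j < n; ++j) {
    tb.u[j] = upper[j];
    for (int i = 0; i < m; ++i) tb.at(i, j) = sign[i] * A(i, j);
  }
  for (int i = 0; i < m; ++i) {
    tb.at(i, n + i) = 1.0;
    tb.basis[i] = n + i;
    tb.xB[i] = sign[i] * b[i];
  }

  int bland_after = 500 + 20 * (m + n);

  // columns fixed at zero can never usefully enter
  std::vector<char> barred1(tb.N, 0), barred2(tb.N, 0);
  for (int j = 0; j < n; ++j)
    if (upper[j] <= TOL) barred1[j] = barred2[j] = 1;

  // phase 1: minimize sum of artificials
  std::vector<double> obj1(tb.N, 0.0);
  for (int i = 0; i < m; ++i) obj1[n + i] = -1.0;
  int st = run_phase(tb, obj1, barred1, maxit, bland_after);
  if (st == 3) return List::create(_["status"] = 3);

  double art_sum = 0.0;
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] >= n) art_sum += tb.xB[i];
  if (art_sum > FEAS_TOL) return List::create(_["status"] = 1);

  // drive residual (degenerate) artificials out of the basis when possible
  for (int i = 0; i < m; ++i) {
    if (tb.basis[i] < n) continue;
    int piv_col = -1;
    for (int j = 0; j < n; ++j) {
      if (barred1[j]) continue;
      if (std::fabs(tb.at(i, j)) > 1e-7) { piv_col = j; break; }
    }
    if (piv_col < 0) continue;  // redundant row; artificial stays at 0
    bool basic_already = false;
    for (int r = 0; r < m; ++r)
      if (tb.basis[r] == piv_col) { basic_already = true; break; }
    if (basic_already) continue;
    // degenerate exchange: drive the (near-zero) artificial to its lower
    // bound, respecting whether the entering column sits at upper bound
    double a_i = tb.at(i, piv_col);
    double s = tb.at_up[piv_col] ? -1.0 : 1.0;
    double t = tb.xB[i] / (s * a_i);  // ~0 since the artificial is ~0
    double enter_val = tb.at_up[piv_col] ? tb.u[piv_col] - t : t;
    for (int r = 0; r < m; ++r) {
      if (r == i) continue;
      tb.xB[r] -= s * t * tb.at(r, piv_col);
    }
    double piv = a_i;
    for (int j = 0; j < tb.N; ++j) tb.at(i, j) /= piv;
    for (int r = 0; r < m; ++r) {
      if (r == i) continue;
      double f = tb.at(r, piv_col);
      if (std::fabs(f) < 1e-13) continue;
      for (int j = 0; j < tb.N; ++j) tb.at(r, j) -= f * tb.at(i, j);
    }
    tb.basis[i] = piv_col;
    tb.at_up[piv_col] = 0;
    tb.xB[i] = enter_val;
  }

  // phase 2: artificials barred
  std::vector<double> obj2(tb.N, 0.0);
  for (int j = 0; j < n; ++j) obj2[j] = c[j];
  for (int i = 0; i < m; ++i) barred2[n + i] = 1;
  st = run_phase(tb, obj2, barred2, maxit, bland_after);
  if (st == 3) return List::create(_["status"] = 3);
  if (st == 2) return List::create(_["status"] = 2);

  NumericVector x(n);
  for (int j = 0; j < n; ++j)
    x[j] = (tb.at_up[j] && std::isfinite(tb.u[j])) ? tb.u[j] : 0.0;
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] < n) x[tb.basis[i]] = tb.xB[i];
  double objval = 0.0;
  for (int j = 0; j < n; ++j) objval += c[j] * x[j];

  return List::create(_["status"] = 0, _["objective"] = objval, _["x"] = x);
}
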