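// Bounded-variable primal simplex for flux balance LPs:
//
//     maximize c'x   subject to   A x = 0,   lb <= x <= ub
//
// Every variable must have lb <= 0 <= ub, so x = 0 is always feasible and no
// phase-1 is needed: the initial basis is a set of artificial columns fixed at
// zero, which leave the basis through degenerate pivots.  The basis inverse is
// maintained by product-form updates with periodic refactorization; Dantzig
// pricing switches to Bland's rule after a long degenerate stall so the
// iteration cannot cycle.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List simplex_box_lp(const arma::vec& c, const arma::mat& A,
                          const arma::vec& lb, const arma::vec& ub,
                          double tol = 1e-9, int max_iter = 50000) {
  const uword m = A.n_rows, n = A.n_cols;
  const uword N = n + m;  // real columns then one artificial per row

  for (uword j = 0; j < n; ++j) {
    if (lb[j] > 1e-12 || ub[j] < -1e-12 || lb[j] > ub[j])
      Rcpp::stop("simplex_box_lp: every variable needs lb <= 0 <= ub");
  }

  vec lbe(N), ube(N), ce(N, fill::zeros);
  lbe.head(n) = lb;  ube.head(n) = ub;
  lbe.tail(m).zeros();  ube.tail(m).zeros();
  ce.head(n) = c;

  vec x(N, fill::zeros);
  uvec basis(m);
  std::vector<char> in_basis(N, 0);
  for (uword i = 0; i < m; ++i) { basis[i] = n + i; in_basis[n + i] = 1; }
  mat Binv(m, m, fill::eye);

  auto colA = [&](uword j) -> vec {
    if (j < n) return A.col(j);
    vec e(m, fill::zeros); e[j - n] = 1.0; return e;
  };

  int status = 0;            // 0 optimal, 1 unbounded, 2 iteration limit
  int since_refactor = 0, degen_streak = 0;
  bool bland = false;
  const double big = std::numeric_limits<double>::infinity();

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // reduced costs via y = Binv' c_B
    vec cB(m);
    for (uword i = 0; i < m; ++i) cB[i] = ce[basis[i]];
    vec y = Binv.t() * cB;

    uword enter = N; int dir = 0; double best = tol;
    for (uword j = 0; j < n; ++j) {          // artificials never re-enter
      if (in_basis[j] || lbe[j] >= ube[j] - 1e-15) continue;
      double dj = ce[j] - dot(y, A.col(j));
      bool can_up = x[j] < ube[j] - 1e-12;
      bool can_dn = x[j] > lbe[j] + 1e-12;
      if (dj > tol && can_up) {
        if (bland) { enter = j; dir = +1; break; }
        if (dj > best) { best = dj; enter = j; dir = +1; }
      } else if (dj < -tol && can_dn) {
        if (bland) { enter = j; dir = -1; break; }
        if (-dj > best) { best = -dj; enter = j; dir = -1; }
      }
    }
    if (enter == N) { status = 0; break; }   // optimal

    vec w = Binv * colA(enter);

    // ratio test: entering moves by dir * theta, basic i changes by -dir*w_i*theta
    double theta_own = (dir > 0) ? (ube[enter] - x[enter]) : (x[enter] - lbe[enter]);
    double theta = theta_own;
    int leave = -1; bool leave_at_upper = false;
    for (uword i = 0; i < m; ++i) {
      double d = -dir * w[i];
      double lim; bool at_upper;
      if (d > 1e-10)       { lim = (ube[basis[i]] - x[basis[i]]) / d; at_upper = true; }
      else if (d < -1e-10) { lim = (lbe[basis[i]] - x[basis[i]]) / d; at_upper = false; }
      else continue;
      if (lim < 0) lim = 0;
      bool take = false;
      if (lim < theta - 1e-12) take = true;
      else if (leave >= 0 && lim < theta + 1e-12 &&
               basis[i] < basis[(uword)leave]) take = true;   // tie: smallest index
      if (take) { theta = lim; leave = (int)i; leave_at_upper = at_upper; }
    }
    if (theta >= big) { status = 1; break; } // cannot happen with finite bounds

    x[enter] += dir * theta;
    for (uword i = 0; i < m; ++i) x[basis[i]] -= dir * w[i] * theta;

    if (leave >= 0 && theta <= theta_own + 1e-12) {
      uword out = basis[(uword)leave];
      x[out] = leave_at_upper ? ube[out] : lbe[out];  // snap to its bound
      in_basis[out] = 0; in_basis[enter] = 1;
      basis[(uword)leave] = enter;
      double piv = w[(uword)leave];
      Binv.row((uword)leave) /= piv;
      for (uword r = 0; r < m; ++r) {
        if (r == (uword)leave) continue;
        Binv.row(r) -= w[r] * Binv.row((uword)leave);
      }
      if (++since_refactor >= 64) {
        mat B(m, m);
        for (uword i = 0; i < m; ++i) B.col(i) = colA(basis[i]);
        Binv = inv(B);
        since_refactor = 0;
      }
    }
    // (otherwise the entering variable just flipped to its opposite bound)

    if (theta < 1e-11) { if (++degen_streak > 2 * (int)(m + n)) bland = true; }
    else degen_streak = 0;
  }
  if (iter >= max_iter) status = 2;

  // refine basic values from the nonbasic ones to kill accumulated drift
  vec rhs(m, fill::zeros);
  for (uword j = 0; j < N; ++j) {
    if (!in_basis[j] && std::abs(x[j]) > 0) rhs -= colA(j) * x[j];
  }
  {
    mat B(m, m);
    for (uword i = 0; i < m; ++i) B.col(i) = colA(basis[i]);
    vec xB;
    bool ok = solve(xB, B, rhs, solve_opts::no_approx);
    if (ok) for (uword i = 0; i < m; ++i) x[basis[i]] = xB[i];
  }

  vec xr = x.head(n);
  return Rcpp::List::create(
    Rcpp::Named("x") = xr,
    Rcpp::Named("objective") = dot(c, xr),
    Rcpp::Named("status") = status,
    Rcpp::Named("iterations") = iter);
}
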