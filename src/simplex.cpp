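// Bounded-variable two-phase revised simplex.
//
// Solves   min c'x   s.t.   A x = b,   lb <= x <= ub   (finite bounds)
//
// Dense revised simplex with an explicitly maintained basis inverse,
// product-form eta updates and periodic refactorisation. Phase 1 drives
// signed artificial variables to zero; redundant (rank-deficient) rows are
// tolerated because their artificials may stay basic at zero with bounds
// clamped to [0, 0] in phase 2. Dantzig pricing with a Bland fallback after
// a long degenerate streak guarantees termination.
//
// Stoichiometric LPs are small-coefficient and well scaled, so a dense
// double-precision kernel with 1e-9 pivot tolerances is adequate; the R
// layer enforces finite bounds (|bound| <= 1e6).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double TOL_D   = 1e-9;   // reduced-cost (dual) tolerance
const double TOL_PIV = 1e-9;   // smallest admissible pivot magnitude
const double TOL_X   = 1e-9;   // primal snapping tolerance
const int    REFACTOR_EVERY = 60;

struct Work {
  const mat& A;            // m x n structural columns
  int m, n, N;             // N = n + m (artificials appended)
  vec lb, ub, x;           // length N
  ivec vstat;              // 0 at lb, 1 at ub, 2 basic (length N)
  ivec basis;              // length m, variable index of each basic slot
  vec art_sign;            // +/-1 per row (artificial column = sign * e_i)
  mat Binv;                // m x m

  Work(const mat& A_) : A(A_) {
    m = A.n_rows; n = A.n_cols; N = n + m;
  }

  // column j of the full constraint matrix
  vec col(int j) const {
    if (j < n) return A.col(j);
    vec e(m, fill::zeros);
    e[j - n] = art_sign[j - n];
    return e;
  }

  void refactor(const vec& b) {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = col(basis[i]);
    mat I_ = eye(m, m);
    bool ok = solve(Binv, B, I_, solve_opts::no_approx);
    if (!ok) Binv = pinv(B);
    // recompute basic values from nonbasic ones
    vec rhs = b;
    for (int j = 0; j < N; ++j)
      if (vstat[j] != 2 && x[j] != 0.0) rhs -= col(j) * x[j];
    vec xb = Binv * rhs;
    for (int i = 0; i < m; ++i) x[basis[i]] = xb[i];
  }
};

// one simplex phase; costs cc over all N variables; allow_enter[j] == false
// blocks a variable from entering (used to freeze artificials in phase 2).
// Returns 0 optimal, 2 iteration trouble.
int run_phase(Work& W, const vec& cc, const std::vector<bool>& allow_enter,
              const vec& b, int max_iter) {
  int since_refactor = 0;
  long degen_streak = 0;
  bool bland = false;
  bool verified = false;  // optimality re-check after a fresh refactor

  for (int iter = 0; iter < max_iter; ++iter) {
    if (since_refactor >= REFACTOR_EVERY) {
      W.refactor(b);
      since_refactor = 0;
    }

    // duals and pricing
    vec cB(W.m);
    for (int i = 0; i < W.m; ++i) cB[i] = cc[W.basis[i]];
    vec y = W.Binv.t() * cB;

    int enter = -1, dir = 0;
    double best = TOL_D;
    for (int j = 0; j < W.N; ++j) {
      if (W.vstat[j] == 2 || !allow_enter[j]) continue;
      if (W.ub[j] - W.lb[j] < TOL_X) continue;  // fixed
      double d = cc[j] - dot(y, W.col(j));
      double viol = (W.vstat[j] == 0) ? -d : d;
      if (viol > best) {
        enter = j; dir = (W.vstat[j] == 0) ? 1 : -1;
        if (bland) break;          // first eligible index
        best = viol;               // Dantzig: most violating
      }
    }

    if (enter < 0) {
      if (verified || since_refactor == 0) return 0;
      W.refactor(b);               // guard against drift before declaring
      since_refactor = 0;          // optimality
      verified = true;
      continue;
    }
    verified = false;

    vec w = W.Binv * W.col(enter);

    // ratio test: x_B changes at rate (-dir * w) per unit step t >= 0
    double tmax = W.ub[enter] - W.lb[enter];  // bound-to-bound flip
    int leave = -1;
    double leave_rate = 0.0;
    int hit = 0;                               // 0 -> lb, 1 -> ub
    for (int i = 0; i < W.m; ++i) {
      double rate = -dir * w[i];
      if (std::abs(rate) <= TOL_PIV) continue;
      int bi = W.basis[i];
      double tt, h;
      if (rate > 0) { tt = (W.ub[bi] - W.x[bi]) / rate; h = 1; }
      else          { tt = (W.lb[bi] - W.x[bi]) / rate; h = 0; }
      if (tt < -TOL_X) tt = 0;
      // prefer strictly smaller ratio; on ties take the larger |pivot|
      if (tt < tmax - 1e-12 ||
          (leave >= 0 && tt < tmax + 1e-12 &&
           std::abs(w[i]) > std::abs(leave_rate))) {
        if (bland && leave >= 0 && tt >= tmax - 1e-12 && W.basis[i] > W.basis[leave])
          continue;                            // Bland: smallest index leaves
        tmax = tt; leave = i; leave_rate = w[i]; hit = (int)h;
      }
    }

    if (!std::isfinite(tmax)) return 2;        // cannot happen with finite bounds
    if (tmax < 0) tmax = 0;

    degen_streak = (tmax <= 1e-11) ? degen_streak + 1 : 0;
    bland = degen_streak > 2L * (W.m + W.n) + 200L;

    // apply the step
    W.x[enter] += dir * tmax;
    for (int i = 0; i < W.m; ++i) W.x[W.basis[i]] += -dir * w[i] * tmax;

    if (leave < 0) {
      W.vstat[enter] = (W.vstat[enter] == 0) ? 1 : 0;
      W.x[enter] = (W.vstat[enter] == 0) ? W.lb[enter] : W.ub[enter];
    } else {
      int lv = W.basis[leave];
      W.vstat[lv] = hit;
      W.x[lv] = (hit == 0) ? W.lb[lv] : W.ub[lv];  // snap
      double piv = w[leave];
      if (std::abs(piv) <= TOL_PIV) { W.refactor(b); since_refactor = 0; continue; }
      W.basis[leave] = enter;
      W.vstat[enter] = 2;
      // Binv <- E^{-1} Binv  (row operations on the leaving row)
      rowvec prow = W.Binv.row(leave) / piv;
      for (int i = 0; i < W.m; ++i) {
        if (i == leave) continue;
        if (w[i] != 0.0) W.Binv.row(i) -= w[i] * prow;
      }
      W.Binv.row(leave) = prow;
      ++since_refactor;
    }
  }
  return 2;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::mat& A, const arma::vec& b,
                         const arma::vec& c, const arma::vec& lb,
                         const arma::vec& ub) {
  const int m = A.n_rows, n = A.n_cols;
  if (m == 0) {
    // unconstrained box problem: each variable sits at its cheaper bound
    vec x(n);
    for (int j = 0; j < n; ++j) x[j] = (c[j] >= 0) ? lb[j] : ub[j];
    return Rcpp::List::create(Rcpp::Named("status") = 0,
                              Rcpp::Named("objective") = dot(c, x),
                              Rcpp::Named("x") = x);
  }

  Work W(A);
  W.lb = join_cols(lb, zeros(m));
  W.ub = join_cols(ub, vec(m, fill::value(datum::inf)));
  W.x  = zeros(W.N);
  W.vstat = ivec(W.N);
  W.basis = ivec(m);
  W.art_sign = vec(m);

  // nonbasic structurals start at the bound of smaller magnitude
  for (int j = 0; j < n; ++j) {
    bool at_lb = std::abs(lb[j]) <= std::abs(ub[j]);
    W.vstat[j] = at_lb ? 0 : 1;
    W.x[j] = at_lb ? lb[j] : ub[j];
  }
  vec r = b - A * W.x.head(n);
  for (int i = 0; i < m; ++i) {
    W.art_sign[i] = (r[i] >= 0) ? 1.0 : -1.0;
    int aj = n + i;
    W.basis[i] = aj;
    W.vstat[aj] = 2;
    W.x[aj] = std::abs(r[i]);
  }
  W.Binv = diagmat(W.art_sign);

  const int max_iter = 20000 + 200 * (W.m + W.n);
  std::vector<bool> allow(W.N, true);

  // phase 1: minimise the artificial mass
  vec c1 = join_cols(zeros(n), ones(m));
  int st = run_phase(W, c1, allow, b, max_iter);
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = 2,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);
  double art_mass = 0;
  for (int i = 0; i < m; ++i) art_mass += W.x[n + i];
  double feas_tol = 1e-7 * (1.0 + norm(b, "inf"));
  if (art_mass > feas_tol)
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);

  // phase 2: freeze artificials at zero (basic ones stay, pinned degenerate)
  for (int i = 0; i < m; ++i) {
    int aj = n + i;
    W.ub[aj] = 0.0;
    if (W.vstat[aj] != 2) W.x[aj] = 0.0;
    allow[aj] = false;
  }
  vec c2 = join_cols(c, zeros(m));
  st = run_phase(W, c2, allow, b, max_iter);
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = 2,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);

  vec xs = W.x.head(n);
  // snap onto bounds to remove sub-tolerance excursions
  for (int j = 0; j < n; ++j) {
    if (xs[j] < lb[j]) xs[j] = lb[j];
    if (xs[j] > ub[j]) xs[j] = ub[j];
  }
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("objective") = dot(c, xs),
                            Rcpp::Named("x") = xs);
}
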