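// ADMM solver for the stability-constrained, L1-budgeted VAR(1) fit
//
//   minimize   0.5 * ||Y - A Z||_F^2
//   subject to sum_jk |a_jk| <= lam
//              a_ii + sum_{j != i} (v_j / v_i) |a_ij| <= 0   for all i
//
// Splitting: X carries the quadratic, B the constraints, with X = B
// enforced by a scaled dual U. The B-update projects onto the
// intersection of the L1 ball and the per-row weighted-Gershgorin sets by
// Dykstra's alternating projections; both elementary projections are
// exact (piecewise-linear root for the rows, sorting for the ball), so
// every reported iterate is feasible up to the inner tolerance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Exact projection of row x onto {a : a_i + sum_{j != i} w_j |a_j| <= 0}
// where w_j = v_j / v_i. KKT: a_i = x_i - theta, a_j = soft(x_j, theta*w_j)
// with theta >= 0 the root of a piecewise-linear decreasing function.
static void project_row(rowvec &x, const uword i, const rowvec &w) {
  const uword n = x.n_elem;
  double g = x(i);
  for (uword j = 0; j < n; ++j)
    if (j != i) g += w(j) * std::fabs(x(j));
  if (g <= 0.0) return;

  std::vector<std::pair<double, uword>> bp;
  bp.reserve(n - 1);
  double level = x(i);  // constant term with current active set
  double slope = 1.0;   // coefficient of theta
  for (uword j = 0; j < n; ++j) {
    if (j == i) continue;
    if (x(j) != 0.0 && w(j) > 0.0) {
      bp.emplace_back(std::fabs(x(j)) / w(j), j);
      level += w(j) * std::fabs(x(j));
      slope += w(j) * w(j);
    }
  }
  std::sort(bp.begin(), bp.end());

  // h(theta) = level - slope * theta on each segment between breakpoints
  double theta = 0.0, prev = 0.0;
  bool found = false;
  for (std::size_t k = 0; k < bp.size(); ++k) {
    const double t = bp[k].first;
    const double root = level / slope;
    if (root <= t) {
      theta = std::max(root, prev);
      found = true;
      break;
    }
    const uword j = bp[k].second;
    level -= w(j) * std::fabs(x(j));
    slope -= w(j) * w(j);
    prev = t;
  }
  if (!found) theta = level / slope;  // past the last breakpoint slope = 1

  for (uword j = 0; j < n; ++j) {
    if (j == i) continue;
    const double m = std::fabs(x(j)) - theta * w(j);
    x(j) = (m > 0.0) ? (x(j) > 0.0 ? m : -m) : 0.0;
  }
  x(i) -= theta;
}

// Exact Euclidean projection onto the L1 ball of radius lam.
static void project_l1(mat &X, const double lam) {
  const double s = accu(abs(X));
  if (s <= lam) return;
  if (lam <= 0.0) {
    X.zeros();
    return;
  }
  vec u = sort(vectorise(abs(X)), "descend");
  vec cs = cumsum(u);
  double tau = 0.0;
  for (uword j = 0; j < u.n_elem; ++j) {
    const double t = (cs(j) - lam) / static_cast<double>(j + 1);
    if (u(j) > t) tau = t;
  }
  for (uword k = 0; k < X.n_elem; ++k) {
    const double m = std::fabs(X(k)) - tau;
    X(k) = (m > 0.0) ? (X(k) > 0.0 ? m : -m) : 0.0;
  }
}

static double row_violation(const mat &X, const mat &W) {
  double viol = 0.0;
  for (uword i = 0; i < X.n_rows; ++i) {
    double gi = X(i, i);
    for (uword j = 0; j < X.n_cols; ++j)
      if (j != i) gi += W(i, j) * std::fabs(X(i, j));
    viol = std::max(viol, gi);
  }
  return viol;
}

// Dykstra's algorithm for the projection onto the intersection of the
// row sets and the L1 ball. The final step is the ball projection, so the
// budget holds exactly and only the row violation needs monitoring.
static mat dykstra_project(const mat &P0, const double lam, const mat &W,
                           const double tol, const int max_iter) {
  mat p = P0;
  mat q1(size(P0), fill::zeros), q2(size(P0), fill::zeros);
  for (int it = 0; it < max_iter; ++it) {
    mat y = p + q1;
    for (uword i = 0; i < y.n_rows; ++i) {
      rowvec r = y.row(i);
      project_row(r, i, W.row(i));
      y.row(i) = r;
    }
    q1 = p + q1 - y;
    mat z = y + q2;
    project_l1(z, lam);
    q2 = y + q2 - z;
    const double change = norm(p - z, "fro");
    p = z;
    if (row_violation(p, W) <= tol && change <= tol) break;
  }
  return p;
}

// [[Rcpp::export(name = ".admm_solve_cpp")]]
Rcpp::List admm_solve_cpp(const arma::mat &Y, const arma::mat &Z,
                          const double lam, const arma::vec &v,
                          const double tol, const int max_iter,
                          Rcpp::Nullable<Rcpp::NumericMatrix> B0 = R_NilValue,
                          Rcpp::Nullable<Rcpp::NumericMatrix> U0 = R_NilValue) {
  const uword N = Y.n_rows;
  const mat G = Z * Z.t();
  const mat C = Y * Z.t();

  mat W(N, N);
  for (uword i = 0; i < N; ++i) W.row(i) = v.t() / v(i);

  mat B(N, N, fill::zeros), U(N, N, fill::zeros);
  if (B0.isNotNull()) B = Rcpp::as<mat>(B0);
  if (U0.isNotNull()) U = Rcpp::as<mat>(U0);

  double rho = std::max(trace(G) / static_cast<double>(N), 1e-3);
  mat F = inv_sympd(G + rho * eye(N, N));

  const double root_n = std::sqrt(static_cast<double>(N * N));
  const double inner_tol = std::min(tol * 1e-1, 1e-9);
  bool converged = false;
  double r_pri = datum::inf, s_dual = datum::inf;
  int it = 0;
  mat X;
  for (it = 1; it <= max_iter; ++it) {
    X = (C + rho * (B - U)) * F;
    const mat B_old = B;
    B = dykstra_project(X + U, lam, W, inner_tol, 2000);
    U += X - B;

    r_pri = norm(X - B, "fro");
    s_dual = rho * norm(B - B_old, "fro");
    const double eps_pri =
        root_n * tol + tol * std::max(norm(X, "fro"), norm(B, "fro"));
    const double eps_dual = root_n * tol + tol * rho * norm(U, "fro");
    if (r_pri <= eps_pri && s_dual <= eps_dual) {
      converged = true;
      break;
    }
    if (it % 25 == 0) {  // residual balancing (Boyd et al. scheme)
      if (r_pri > 10.0 * s_dual) {
        rho *= 2.0;
        U /= 2.0;
        F = inv_sympd(G + rho * eye(N, N));
      } else if (s_dual > 10.0 * r_pri && rho > 1e-8) {
        rho /= 2.0;
        U *= 2.0;
        F = inv_sympd(G + rho * eye(N, N));
      }
    }
  }

  const double obj = 0.5 * accu(square(Y - B * Z));
  return Rcpp::List::create(
      Rcpp::Named("A") = B, Rcpp::Named("U") = U,
      Rcpp::Named("objective") = obj, Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("primal_residual") = r_pri,
      Rcpp::Named("dual_residual") = s_dual,
      Rcpp::Named("row_violation") = row_violation(B, W),
      Rcpp::Named("l1_norm") = accu(abs(B)));
}
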