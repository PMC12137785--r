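// Magnitude-least-squares core for kT-points design.
//
// The MLS cost is sum_r (|A_r w| - theta)^2 + lambda ||w||^2, minimized by
// variable exchange: fix the target phases at arg(A w), solve the resulting
// regularized linear least-squares problem, repeat. Both half-steps decrease
// the joint cost, so the MLS cost trace is non-increasing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double mls_cost(const cx_vec& z, double theta, double lambda,
                       const cx_vec& w) {
  vec m = abs(z);
  return accu(square(m - theta)) + lambda * std::real(cdot(w, w));
}

// unit phases of z; zero entries map to phase 1
static cx_vec unit_phase(const cx_vec& z) {
  vec m = abs(z);
  cx_vec u(z.n_elem);
  for (uword i = 0; i < z.n_elem; ++i)
    u(i) = m(i) > 0 ? z(i) / m(i) : cx_double(1.0, 0.0);
  return u;
}

// solve (A^H A + lambda I) w = rhs with a pseudo-inverse fallback for the
// unregularized rank-deficient case (e.g. duplicated kT-points at lambda 0)
static cx_vec solve_normal(const cx_mat& AhA, const cx_vec& rhs) {
  cx_vec w;
  bool ok = solve(w, AhA, rhs, solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) w = pinv(AhA) * rhs;
  return w;
}

struct VEResult {
  cx_vec w;
  vec trace;
  double cost;
};

static VEResult run_ve(const cx_mat& A, double theta, double lambda,
                       cx_vec w, double tol, int maxit) {
  cx_mat AhA = A.t() * A;  // conjugate transpose
  AhA.diag() += lambda;
  std::vector<double> tr;
  cx_vec z = A * w;
  double cost = mls_cost(z, theta, lambda, w);
  tr.push_back(cost);
  for (int it = 0; it < maxit; ++it) {
    cx_vec b = theta * unit_phase(z);
    cx_vec rhs = A.t() * b;
    w = solve_normal(AhA, rhs);
    z = A * w;
    double nc = mls_cost(z, theta, lambda, w);
    tr.push_back(nc);
    if (std::fabs(cost - nc) <= tol * std::max(cost, 1e-300)) {
      cost = nc;
      break;
    }
    cost = nc;
  }
  VEResult out;
  out.w = w;
  out.trace = vec(tr);
  out.cost = cost;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_mls_ve(const arma::cx_mat& A, double theta, double lambda,
                      const arma::cx_vec& w0, double tol, int maxit) {
  VEResult r = run_ve(A, theta, lambda, w0, tol, maxit);
  return Rcpp::List::create(Rcpp::Named("weights") = r.w,
                            Rcpp::Named("costTrace") = r.trace,
                            Rcpp::Named("cost") = r.cost);
}

// STA system matrix: columns grouped by kT-point, channel fastest.
// B: nvox x C (already scaled by c0), pos: nvox x 3 (m), k: K x 3 (rad/m).
// [[Rcpp::export]]
arma::cx_mat cpp_sta_matrix(const arma::cx_mat& B, const arma::mat& pos,
                            const arma::mat& k) {
  uword n = B.n_rows, C = B.n_cols, K = k.n_rows;
  cx_mat A(n, C * K);
  for (uword j = 0; j < K; ++j) {
    vec ph = pos * k.row(j).t();
    cx_vec ramp(n);
    for (uword i = 0; i < n; ++i)
      ramp(i) = cx_double(std::cos(ph(i)), std::sin(ph(i)));
    for (uword c = 0; c < C; ++c)
      A.col(j * C + c) = B.col(c) % ramp;
  }
  return A;
}

// Greedy candidate scan: for each candidate phase-ramp column set
// [Abase, B .* E_j], run variable exchange from [wbase; 0] and report the
// final MLS cost. E: nvox x ncand complex unit ramps.
// [[Rcpp::export]]
arma::vec cpp_greedy_scan(const arma::cx_mat& Abase, const arma::cx_mat& B,
                          const arma::cx_mat& E, double theta, double lambda,
                          const arma::cx_vec& wbase, double tol, int maxit) {
  uword n = B.n_rows, C = B.n_cols, m0 = Abase.n_cols;
  uword ncand = E.n_cols;
  vec costs(ncand);
  cx_mat A(n, m0 + C);
  if (m0 > 0) A.cols(0, m0 - 1) = Abase;
  cx_vec w0(m0 + C, fill::zeros);
  if (m0 > 0) w0.head(m0) = wbase;
  for (uword j = 0; j < ncand; ++j) {
    for (uword c = 0; c < C; ++c)
      A.col(m0 + c) = B.col(c) % E.col(j);
    VEResult r = run_ve(A, theta, lambda, w0, tol, maxit);
    costs(j) = r.cost;
  }
  return costs;
}
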