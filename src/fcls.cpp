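// Fully constrained least-squares (FCLS) spectral unmixing.
//
// Per pixel we minimise ||rho - E' a||^2 subject to a >= 0 and sum(a) = 1.
// The sum-to-one constraint is carried as an extra heavily weighted row
// (delta * 1' a = delta) appended to the design, and the augmented
// non-negative least-squares problem is solved with the Lawson-Hanson
// active-set iteration; the solution is then renormalised so the simplex
// constraint holds exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson NNLS: minimise ||A x - b|| subject to x >= 0.
static vec nnls(const mat& A, const vec& b) {
  const uword n = A.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * (b - A * x);
  const double tol = 1e-12 * std::max(1.0, norm(b));
  const uword maxit = 30 * n;

  for (uword it = 0; it < maxit; ++it) {
    // most violated dual among the active (zero) set
    double wmax = tol;
    sword jmax = -1;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    }
    if (jmax < 0) break;  // KKT satisfied
    passive[jmax] = true;

    for (uword inner = 0; inner < maxit; ++inner) {
      uvec P(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec z;
      if (!solve(z, A.cols(P), b)) {
        // near-singular passive set: minimum-norm solution
        z = pinv(A.cols(P)) * b;
      }
      if (z.min() > 0) {
        x.zeros();
        x(P) = z;
        break;
      }
      // step toward z until the first passive variable hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k) {
        if (z(k) <= 0) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      }
      for (uword k = 0; k < np; ++k) {
        x(P(k)) += alpha * (z(k) - x(P(k)));
        if (x(P(k)) <= tol) { x(P(k)) = 0; passive[P(k)] = false; }
      }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// Batch FCLS over pixels.
// R: B x P matrix of pixel reflectance spectra (one column per pixel)
// E: N x B endmember reference matrix
// Returns N x P abundances and length-P residual norms (in band space).
// [[Rcpp::export]]
Rcpp::List fcls_batch_cpp(const arma::mat& R, const arma::mat& E,
                          double delta) {
  const uword B = E.n_cols, N = E.n_rows, P = R.n_cols;
  if (R.n_rows != B) Rcpp::stop("spectrum length does not match the library");
  mat A(B + 1, N);
  A.rows(0, B - 1) = E.t();
  A.row(B).fill(delta);

  mat abund(N, P);
  vec resid(P);
  vec b(B + 1);
  b(B) = delta;
  for (uword p = 0; p < P; ++p) {
    b.subvec(0, B - 1) = R.col(p);
    vec x = nnls(A, b);
    double s = accu(x);
    if (s > 0) {
      x /= s;
    } else {
      x.fill(1.0 / N);  // degenerate: flat prior on the simplex
    }
    abund.col(p) = x;
    resid(p) = norm(R.col(p) - E.t() * x);
  }
  return Rcpp::List::create(Rcpp::Named("abundance") = abund,
                            Rcpp::Named("residual_norm") = resid);
}

// Exhaustive simplex-lattice search, independent of the solver above; used
// as a brute-force oracle. Enumerates all abundance vectors with entries
// k/steps summing to 1 and returns the minimal squared residual.
static double grid_rec(const mat& Et, vec part, uword d, int rem, int steps) {
  const uword N = Et.n_cols;
  if (d == N - 1) {
    part -= (double(rem) / steps) * Et.col(d);
    return dot(part, part);
  }
  double best = datum::inf;
  vec cur = part;
  const vec stepcol = Et.col(d) / steps;
  for (int k = 0; k <= rem; ++k) {
    double v = grid_rec(Et, cur, d + 1, rem - k, steps);
    if (v < best) best = v;
    cur -= stepcol;
  }
  return best;
}

// [[Rcpp::export]]
double fcls_grid_objective_cpp(const arma::vec& r, const arma::mat& E,
                               int steps) {
  if (E.n_cols != r.n_elem) Rcpp::stop("spectrum length does not match the library");
  return grid_rec(E.t(), r, 0, steps, steps);
}
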