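// Homogeneous McConnell propagation for CW-saturation (DEST) experiments.
//
// States exchange according to a first-order rate matrix K (columns:
// origin state, rows: destination; diagonal = -sum of leaving rates).
// Each state carries (Mx, My, Mz); longitudinal relaxation drives Mz of
// state i toward its stationary population p0[i], which is folded into a
// homogeneous constant row so the whole evolution is a single matrix
// exponential over the saturation time.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build the (3n+1) x (3n+1) evolution matrix for one saturation offset.
// delta: offset of the resonance from the saturation carrier (rad/s)
// omega1: saturation field amplitude (rad/s), along x
// r1: longitudinal rate shared by all states (1/s)
// r2: per-state transverse rates (1/s)
// K: n x n exchange rate matrix (1/s)
// p0: stationary populations (sum 1)
static mat evolution_matrix(double delta, double omega1, double r1,
                            const vec& r2, const mat& K, const vec& p0) {
  const uword n = r2.n_elem;
  mat A(3 * n + 1, 3 * n + 1, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    const uword x = 3 * i, y = 3 * i + 1, z = 3 * i + 2;
    // Bloch block in the saturation rotating frame
    A(x, x) -= r2(i);  A(x, y) += delta;
    A(y, x) -= delta;  A(y, y) -= r2(i);  A(y, z) += omega1;
    A(z, y) -= omega1; A(z, z) -= r1;
    A(z, 3 * n) += r1 * p0(i);  // recovery toward p0 via homogeneous row
    // exchange couples like components of all states
    for (uword j = 0; j < n; ++j) {
      A(x, 3 * j)     += K(i, j);
      A(y, 3 * j + 1) += K(i, j);
      A(z, 3 * j + 2) += K(i, j);
    }
  }
  return A;
}

//' @name mcconnell_z
//' @noRd
// [[Rcpp::export]]
arma::vec mcconnell_z_cpp(const arma::vec& delta, double omega1, double tsat,
                          double r1, const arma::vec& r2, const arma::mat& K,
                          const arma::vec& p0, int state) {
  const uword n = r2.n_elem;
  if (K.n_rows != n || K.n_cols != n || p0.n_elem != n)
    Rcpp::stop("inconsistent state dimensions");
  if (state < 1 || (uword)state > n) Rcpp::stop("bad state index");
  vec m0(3 * n + 1, fill::zeros);
  for (uword i = 0; i < n; ++i) m0(3 * i + 2) = p0(i);
  m0(3 * n) = 1.0;
  vec out(delta.n_elem);
  for (uword k = 0; k < delta.n_elem; ++k) {
    mat A = evolution_matrix(delta(k), omega1, r1, r2, K, p0);
    mat E;
    const bool ok = expmat(E, A * tsat);
    if (!ok || !E.is_finite())
      Rcpp::stop("matrix-exponential propagation failed (stiff system)");
    vec m = E * m0;
    out(k) = m(3 * (state - 1) + 2);
  }
  return out;
}

// Full final magnetization vector at a single offset (used by tests).
// [[Rcpp::export]]
arma::vec mcconnell_state_cpp(double delta, double omega1, double tsat,
                              double r1, const arma::vec& r2,
                              const arma::mat& K, const arma::vec& p0) {
  const uword n = r2.n_elem;
  vec m0(3 * n + 1, fill::zeros);
  for (uword i = 0; i < n; ++i) m0(3 * i + 2) = p0(i);
  m0(3 * n) = 1.0;
  mat E;
  if (!expmat(E, evolution_matrix(delta, omega1, r1, r2, K, p0) * tsat))
    Rcpp::stop("matrix-exponential propagation failed (stiff system)");
  return E * m0;
}
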