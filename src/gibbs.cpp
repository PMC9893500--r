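// Bivariate pedigree animal model Gibbs sampler.
//
// Model, per trait t in {1,2}:
//   y_t = X b_t + Z u_t + e_t
// with u = (u_1', u_2')' ~ N(0, G0 (x) A) over the q pedigree animals and
// record-wise residual pairs e_i ~ N(0, R0) (every phenotyped animal carries
// both traits, so residuals are correlated across traits within animal).
// Conjugate draws: matrix-normal block for the fixed effects, single-site
// bivariate normal updates per animal for u using A^{-1}, inverse-Wishart
// full conditionals for G0 and R0. All randomness comes from R's RNG so
// set.seed() in R makes chains reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat chol_lower_safe(const mat& S) {
  mat L;
  mat Sj = S;
  double jit = 1e-10 * (1.0 + trace(S) / S.n_rows);
  for (int k = 0; k < 8; ++k) {
    if (chol(L, Sj, "lower")) return L;
    Sj.diag() += jit;
    jit *= 10.0;
  }
  Rcpp::stop("covariance draw not positive definite after jitter");
}

// G ~ InvWishart(S, df) via Bartlett on W ~ Wishart(df, S^{-1}), G = W^{-1}
static mat riwish2(const mat& S, double df) {
  mat L = chol_lower_safe(inv_sympd(symmatu(S)));
  mat A(2, 2, fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = R::rnorm(0.0, 1.0);
  mat LA = L * A;
  mat W = LA * LA.t();
  return inv_sympd(symmatu(W));
}

// [[Rcpp::export(name = ".gibbs_bivariate_cpp")]]
Rcpp::List gibbs_bivariate_cpp(const arma::mat& Y, const arma::mat& X,
                               const arma::ivec& animal, const arma::mat& Ainv,
                               const arma::mat& Sg, double nug,
                               const arma::mat& Sr, double nur,
                               int n_iter, int burn_in, int thin) {
  const int n = Y.n_rows;
  const int p = X.n_cols;
  const int q = Ainv.n_rows;
  if ((int)animal.n_elem != n) Rcpp::stop("animal index length mismatch");
  if (burn_in >= n_iter) Rcpp::stop("burn_in must be < n_iter");
  if (thin < 1) Rcpp::stop("thin must be >= 1");

  Rcpp::RNGScope scope;

  // record index per pedigree animal (-1 = unphenotyped)
  ivec rec_of(q); rec_of.fill(-1);
  for (int r = 0; r < n; ++r) {
    int a = animal(r) - 1;
    if (a < 0 || a >= q) Rcpp::stop("animal index out of range");
    rec_of(a) = r;
  }

  mat XtX = X.t() * X;
  mat XtXinv = inv_sympd(symmatu(XtX));
  mat Lx = chol_lower_safe(XtXinv);

  mat B(p, 2, fill::zeros);
  mat U(q, 2, fill::zeros);
  mat G0 = Sg / std::max(nug, 3.0);
  mat R0 = Sr / std::max(nur, 3.0);

  const int n_keep = (n_iter - burn_in) / thin;
  mat out(n_keep, 6);
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- fixed effects: matrix-normal draw given u, R0 -----------------
    mat Ystar = Y;
    for (int r = 0; r < n; ++r) Ystar.row(r) -= U.row(animal(r) - 1);
    mat Bhat = XtXinv * (X.t() * Ystar);
    mat Zb(p, 2);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < 2; ++j) Zb(i, j) = R::rnorm(0.0, 1.0);
    mat Lr = chol_lower_safe(R0);
    B = Bhat + Lx * Zb * Lr.t();

    mat W = X * B;
    mat Ginv = inv_sympd(symmatu(G0));
    mat Rinv = inv_sympd(symmatu(R0));

    // --- breeding values: single-site bivariate updates ----------------
    // 2x2 algebra unrolled; D is SPD so its inverse and the lower Cholesky
    // factor of the inverse have closed forms
    {
      const double g11 = Ginv(0, 0), g12 = Ginv(0, 1), g22 = Ginv(1, 1);
      const double r11 = Rinv(0, 0), r12 = Rinv(0, 1), r22 = Rinv(1, 1);
      const double* ai = Ainv.memptr();
      const double* u0 = U.colptr(0);
      const double* u1 = U.colptr(1);
      for (int i = 0; i < q; ++i) {
        const double* arow = ai + (size_t)i * q; // Ainv is symmetric
        double s0 = 0.0, s1 = 0.0;
        for (int j = 0; j < q; ++j) {
          s0 += arow[j] * u0[j];
          s1 += arow[j] * u1[j];
        }
        const double aii = arow[i];
        s0 -= aii * u0[i];
        s1 -= aii * u1[i];
        double d11 = aii * g11, d12 = aii * g12, d22 = aii * g22;
        double rhs0 = -(g11 * s0 + g12 * s1);
        double rhs1 = -(g12 * s0 + g22 * s1);
        int r = rec_of(i);
        if (r >= 0) {
          d11 += r11; d12 += r12; d22 += r22;
          const double e0 = Y(r, 0) - W(r, 0);
          const double e1 = Y(r, 1) - W(r, 1);
          rhs0 += r11 * e0 + r12 * e1;
          rhs1 += r12 * e0 + r22 * e1;
        }
        const double det = d11 * d22 - d12 * d12;
        const double v11 = d22 / det, v12 = -d12 / det, v22 = d11 / det;
        const double mu0 = v11 * rhs0 + v12 * rhs1;
        const double mu1 = v12 * rhs0 + v22 * rhs1;
        const double l11 = std::sqrt(v11);
        const double l21 = v12 / l11;
        const double l22 = std::sqrt(v22 - l21 * l21);
        const double z0 = R::rnorm(0.0, 1.0);
        const double z1 = R::rnorm(0.0, 1.0);
        U(i, 0) = mu0 + l11 * z0;
        U(i, 1) = mu1 + l21 * z0 + l22 * z1;
      }
    }

    // --- (co)variance components ---------------------------------------
    mat Sg_post = Sg + U.t() * Ainv * U;
    G0 = riwish2(symmatu(Sg_post), nug + q);

    mat E = Y - W;
    for (int r = 0; r < n; ++r) E.row(r) -= U.row(animal(r) - 1);
    mat Sr_post = Sr + E.t() * E;
    R0 = riwish2(symmatu(Sr_post), nur + n);

    if (!G0.is_finite() || !R0.is_finite())
      Rcpp::stop("sampler diverged (non-finite draw) at iteration %d", iter);

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      out(kept, 0) = G0(0, 0);
      out(kept, 1) = G0(0, 1);
      out(kept, 2) = G0(1, 1);
      out(kept, 3) = R0(0, 0);
      out(kept, 4) = R0(0, 1);
      out(kept, 5) = R0(1, 1);
      ++kept;
    }
  }

  return Rcpp::List::create(Rcpp::Named("samples") = out,
                            Rcpp::Named("n_stored") = kept);
}
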