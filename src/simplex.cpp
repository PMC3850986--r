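// Dense primal simplex for the 1-norm (LASSO-style) hinge-loss linear
// program:
//
//   minimize   lambda * sum_k (u_k + v_k) + sum_i xi_i
//   subject to y_i ((u - v) . x_i + bp - bm) + xi_i >= 1,
//              u, v, bp, bm, xi >= 0,
//
// with w = u - v and intercept b = bp - bm. In equality form (surplus
// variables s_i) the xi columns are an identity and xi = 1 is a basic
// feasible start, so no Phase-I is needed; costs are non-negative, so the
// program is bounded below by zero and never unbounded.
//
// Two structural economies keep the tableau small and the run fast:
//
//  * Twin columns. v_k = -u_k, bm = -bp and s_i = -xi_i column-wise, and
//    B^{-1} is linear, so the tableau only stores the p + 1 + m unique
//    columns [u | bp | xi]; each twin is the stored column negated, with
//    reduced cost r^- = (c^- + c^+) - r^+. A twin of a basic variable can
//    never price negative (its reduced cost is 2*lambda, 0, or 1), so the
//    dependent pair never enters a basis together.
//
//  * Degeneracy. The all-ones RHS makes hinge LPs on binary designs
//    massively degenerate; a tiny deterministic RHS perturbation breaks
//    ratio-test ties, and after optimality the final basis is re-solved
//    exactly against the unperturbed RHS (reduced costs do not depend on
//    the RHS, so the optimality certificate is unaffected and the
//    reported optimum carries no perturbation error).
//
// Pricing is Devex (Forrest-Goldfarb reference weights, shared by twin
// columns since the weight approximates ||B^{-1}a_j||^2 and is
// sign-invariant) over both signs, with a Bland fallback after a pivot
// budget, the classical anti-cycling safeguard. Binary hinge designs are
// heavily dual-degenerate and plain Dantzig pricing zigzags on them;
// Devex cuts the pivot counts by an order of magnitude.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".one_norm_lp_cpp")]]
Rcpp::List one_norm_lp_cpp(const arma::mat& X, const arma::vec& y,
                           const double lambda, const double tol = 1e-9,
                           const double perturb = 1e-7) {
  const uword m = X.n_rows, p = X.n_cols;
  const uword n = p + 1 + m;           // stored columns: u_k, bp, xi_i

  mat T(m, n);
  for (uword k = 0; k < p; ++k) T.col(k) = y % X.col(k);
  T.col(p) = y;
  T.cols(p + 1, n - 1) = eye(m, m);

  // costs of the stored (+) columns and of their negated twins
  vec cpos(n), cneg(n);
  cpos.subvec(0, p - 1).fill(lambda);  cneg.subvec(0, p - 1).fill(lambda);
  cpos(p) = 0.0;                       cneg(p) = 0.0;
  cpos.subvec(p + 1, n - 1).fill(1.0); cneg.subvec(p + 1, n - 1).fill(0.0);
  const vec csum = cpos + cneg;        // r^- = csum - r^+

  // deterministic multiplicative RHS perturbation (LCG), breaks ties
  vec xb(m);
  unsigned long state = 88172645463325252ULL ^ (unsigned long) (m * 2654435761ULL);
  for (uword i = 0; i < m; ++i) {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    xb(i) = 1.0 + perturb * (0.5 + (double) ((state >> 33) & 0xffffff) / 0x1000000);
  }

  uvec basis = regspace<uvec>(p + 1, n - 1);  // xi basis, all sign +1
  ivec bsign(m, fill::ones);
  // r^+ = c^+ - c_B' T with c_B = 1: column sums
  rowvec rpos = cpos.t() - sum(T, 0);

  const uword max_iter = 20000 + 40 * (m + p);
  const uword bland_after = max_iter / 2;
  uword iter = 0;
  int status = 1;                      // 1 = iteration limit, 0 = optimal

  rowvec gamma(n, fill::ones);         // Devex reference weights
  vec col(m);
  for (; iter < max_iter; ++iter) {
    // entering: largest r^2 / gamma over both signs (Devex)
    uword j = n; int sgn = 1; double rbest = 0.0, sbest = 0.0;
    if (iter < bland_after) {
      for (uword q = 0; q < n; ++q) {
        const double rp = rpos(q);
        if (rp < -tol) {
          const double sc = rp * rp / gamma(q);
          if (sc > sbest) { sbest = sc; rbest = rp; j = q; sgn = 1; }
        }
        const double rneg = csum(q) - rp;
        if (rneg < -tol) {
          const double sc = rneg * rneg / gamma(q);
          if (sc > sbest) { sbest = sc; rbest = rneg; j = q; sgn = -1; }
        }
      }
    } else {                           // Bland: first eligible
      for (uword q = 0; q < n && j == n; ++q) {
        if (rpos(q) < -tol) { j = q; sgn = 1; rbest = rpos(q); }
        else if (csum(q) - rpos(q) < -tol) { j = q; sgn = -1; rbest = csum(q) - rpos(q); }
      }
    }
    if (j == n) { status = 0; break; }

    col = (sgn > 0) ? T.col(j) : vec(-T.col(j));
    uword i = m; double best = datum::inf;
    for (uword q = 0; q < m; ++q) {
      if (col(q) > tol) {
        const double ratio = xb(q) / col(q);
        if (ratio < best) { best = ratio; i = q; }
      }
    }
    if (i == m) { status = 2; break; } // unbounded: cannot happen (c >= 0)

    // One fused pass over the columns: rank-1 tableau update (binary
    // designs leave many exact zeros in the pivot row, whose columns can
    // be skipped entirely), reduced-cost update
    // r_new(a) = r_old(a) - r_e * (B_new^{-1}a)_i, and the Devex weight
    // update gamma_j = max(gamma_j, alpha_j^2 gamma_q). Hand-rolled to
    // avoid the m x n temporary an outer-product expression would create.
    const double piv = col(i);
    const double pxb = xb(i) / piv;
    const double gq = gamma(j);
    col(i) = 0.0;
    double gmax = 0.0;
    const double* cp = col.memptr();
    for (uword q = 0; q < n; ++q) {
      double* tc = T.colptr(q);
      const double f = tc[i] / piv;
      if (f != 0.0) {
        for (uword r2 = 0; r2 < m; ++r2) tc[r2] -= f * cp[r2];
        tc[i] = f;
        rpos(q) -= rbest * f;
        const double g2 = f * f * gq;
        if (g2 > gamma(q)) gamma(q) = g2;
      }
      if (gamma(q) > gmax) gmax = gamma(q);
    }
    for (uword r2 = 0; r2 < m; ++r2) xb(r2) -= pxb * cp[r2];
    xb(i) = pxb;
    gamma(j) = std::max(gq / (piv * piv), 1.0);
    if (gmax > 1e12) gamma.ones();   // new Devex reference frame
    basis(i) = j;
    bsign(i) = sgn;
  }

  // exact re-solve of the final basis against the unperturbed RHS
  mat B(m, m);
  for (uword q = 0; q < m; ++q) {
    vec a(m);
    const uword bq = basis(q);
    if (bq < p) a = y % X.col(bq);
    else if (bq == p) a = y;
    else { a.zeros(); a(bq - p - 1) = 1.0; }
    B.col(q) = (bsign(q) > 0) ? a : vec(-a);
  }
  vec zb;
  const bool ok = solve(zb, B, ones<vec>(m));
  if (!ok && status == 0) status = 3;
  if (ok) zb.clamp(0.0, datum::inf);

  vec w(p, fill::zeros);
  double b = 0.0, obj = 0.0;
  if (ok) {
    for (uword q = 0; q < m; ++q) {
      const uword bq = basis(q);
      const double val = (bsign(q) > 0) ? zb(q) : -zb(q);
      if (bq < p) w(bq) = val;
      else if (bq == p) b = val;
      obj += ((bsign(q) > 0) ? cpos(bq) : cneg(bq)) * zb(q);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("w") = w, Rcpp::Named("b") = b,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("status") = status,
    Rcpp::Named("iterations") = (int) iter);
}
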