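// Newton / Fisher-scoring fit of the convolutional Poisson GLM.
// The design matrix arrives as a dgCMatrix (kernel-lag columns, no
// intercept); the intercept is handled explicitly. Counts are per-bin
// spike counts; the objective is sum(mu) - sum(r * eta) with
// eta = b0 + X beta + log(delta), mu = exp(eta).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double nll_of(const vec& eta, const vec& r) {
  if (!eta.is_finite() || eta.max() > 700.0)
    return datum::inf;
  return accu(exp(eta)) - dot(r, eta);
}

// [[Rcpp::export(name = ".irls_fit_cpp")]]
Rcpp::List irls_fit_cpp(const arma::sp_mat& X, const arma::vec& r,
                        arma::vec beta, double log_delta, double rel_tol,
                        double grad_tol, int max_iter,
                        double eta_cap_counts) {
  const uword p = X.n_cols;
  if (beta.n_elem != p + 1)
    Rcpp::stop("beta has the wrong length");

  vec beta_k = beta.subvec(1, p);
  double b0 = beta(0);

  vec eta = b0 + X * beta_k + log_delta;
  double nll = nll_of(eta, r);
  bool converged = false;
  int it = 0;
  double grad_max = datum::inf;

  // CSC skeleton of X, reused to build the row-weighted design each
  // iteration (direct array construction; element writes through sp_mat
  // iterators are far too slow)
  const uword nnz = X.n_nonzero;
  uvec rind(nnz), cptr(p + 1);
  for (uword j = 0; j <= p; ++j) cptr(j) = X.col_ptrs[j];
  for (uword k = 0; k < nnz; ++k) rind(k) = X.row_indices[k];
  vec wvals(nnz);

  while (it < max_iter) {
    ++it;
    vec mu = exp(eta);
    vec resid = mu - r;
    vec grad(p + 1);
    grad(0) = accu(resid);
    grad.subvec(1, p) = X.t() * resid;
    grad_max = abs(grad).max();
    if (grad_max < grad_tol) { converged = true; break; }

    vec w = clamp(mu, 0.0, eta_cap_counts);   // cap runaway IRLS weights
    vec sw = sqrt(w);

    for (uword k = 0; k < nnz; ++k)
      wvals(k) = X.values[k] * sw(X.row_indices[k]);
    sp_mat Xw(rind, cptr, wvals, X.n_rows, p);
    mat A(p + 1, p + 1);
    A.submat(1, 1, p, p) = mat(Xw.t() * Xw);
    vec xw = X.t() * w;
    A(0, 0) = accu(w);
    A.submat(1, 0, p, 0) = xw;
    A.submat(0, 1, 0, p) = xw.t();

    // tiny relative damping keeps the Cholesky viable when lag columns
    // are numerically collinear; the step still targets the exact MLE
    double damp = 1e-8 * A.diag().max();
    vec step;
    bool ok = false;
    for (int tries = 0; tries < 4 && !ok; ++tries) {
      mat R;
      if (chol(R, A + damp * eye(p + 1, p + 1))) {
        step = solve(trimatu(R), solve(trimatl(R.t()), -grad));
        ok = step.is_finite();
      }
      damp *= 100.0;
    }
    if (!ok)
      step = -grad / std::max(1.0, norm(grad));

    // step-halving line search on the exact NLL
    double alpha = 1.0;
    double b0_new = b0;
    vec beta_new = beta_k, eta_new = eta;
    double nll_new = nll;
    while (true) {
      b0_new = b0 + alpha * step(0);
      beta_new = beta_k + alpha * step.subvec(1, p);
      eta_new = b0_new + X * beta_new + log_delta;
      nll_new = nll_of(eta_new, r);
      if (std::isfinite(nll_new) && nll_new <= nll + 1e-12) break;
      alpha *= 0.5;
      if (alpha < 1e-10) {  // no improving step found
        b0_new = b0; beta_new = beta_k; eta_new = eta; nll_new = nll;
        break;
      }
    }
    double moved = nll - nll_new;
    b0 = b0_new; beta_k = beta_new; eta = eta_new;
    if (moved < rel_tol * (std::abs(nll) + 1.0)) {
      nll = nll_new; converged = true; break;
    }
    nll = nll_new;
  }

  vec mu = exp(eta);
  vec resid = mu - r;
  vec grad(p + 1);
  grad(0) = accu(resid);
  grad.subvec(1, p) = X.t() * resid;
  grad_max = abs(grad).max();
  if (grad_max < grad_tol) converged = true;

  vec out(p + 1);
  out(0) = b0;
  out.subvec(1, p) = beta_k;
  return Rcpp::List::create(
    Rcpp::Named("beta") = out,
    Rcpp::Named("nll") = nll,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = it,
    Rcpp::Named("gradient_max") = grad_max);
}
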