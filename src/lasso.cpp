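// Coordinate-descent LASSO path and leave-one-out cross-validation.
//
// Covariance-update form: predictors are standardised to zero mean and unit
// (population) SD, the response is centred, and the objective
//   (1/2n) ||y - Z b||^2 + lambda ||b||_1
// is minimised per lambda with warm starts down the path. Coefficients are
// reported back on the original predictor scale. The LOOCV loop rebuilds the
// per-fold Gram matrix by rank-one downdate of the full-data sums, so the
// held-out fit is exact, not approximate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Solve the standardised problem for all lambdas (decreasing), warm-started.
// G: p x p Gram (Z'Z / n), cvec: Z'yc / n. Returns p x nlam matrix; iters
// records coordinate sweeps per lambda.
static mat cd_path(const mat& G, const vec& cvec, const vec& lambda,
                   double tol, int maxit, ivec& iters) {
  const uword p = G.n_rows, nlam = lambda.n_elem;
  mat B(p, nlam, fill::zeros);
  vec b(p, fill::zeros);
  vec Gb(p, fill::zeros);  // G * b, maintained incrementally
  for (uword l = 0; l < nlam; ++l) {
    const double lam = lambda(l);
    int it = 0;
    for (; it < maxit; ++it) {
      double maxdel = 0.0;
      for (uword j = 0; j < p; ++j) {
        const double gjj = G(j, j);
        if (gjj <= 0) { b(j) = 0; continue; }
        const double z = cvec(j) - Gb(j) + gjj * b(j);
        const double bj = soft(z, lam) / gjj;
        const double del = bj - b(j);
        if (del != 0.0) {
          Gb += del * G.col(j);
          b(j) = bj;
          double ad = std::abs(del);
          if (ad > maxdel) maxdel = ad;
        }
      }
      if (maxdel < tol * std::max(1.0, norm(b, "inf"))) break;
    }
    iters(l) = it + 1;
    B.col(l) = b;
  }
  return B;
}

// [[Rcpp::export]]
Rcpp::List lasso_path_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::vec& lambda, double tol, int maxit) {
  const uword n = X.n_rows, p = X.n_cols;
  rowvec xm = mean(X, 0);
  rowvec xs = sqrt(mean(square(X.each_row() - xm), 0));  // population SD
  uvec keep = find(xs > 0);
  rowvec xs_safe = xs;
  xs_safe.elem(find(xs <= 0)).fill(1.0);
  mat Z = (X.each_row() - xm).each_row() / xs_safe;
  Z.cols(find(xs <= 0)).zeros();
  const double ym = mean(y);
  vec yc = y - ym;
  mat G = Z.t() * Z / double(n);
  vec cvec = Z.t() * yc / double(n);
  ivec iters(lambda.n_elem, fill::zeros);
  mat B = cd_path(G, cvec, lambda, tol, maxit, iters);
  // back-transform to the original scale
  mat beta = B.each_col() / xs_safe.t();
  beta.rows(find(xs <= 0)).zeros();
  rowvec a0 = ym - xm * beta;
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta, Rcpp::Named("intercept") = a0.t(),
      Rcpp::Named("lambda") = lambda, Rcpp::Named("iterations") = iters,
      Rcpp::Named("lambda_max") = cvec.is_empty() ? 0.0 : abs(cvec).max());
}

// [[Rcpp::export]]
arma::mat loocv_sqerr_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::vec& lambda, double tol, int maxit) {
  const uword n = X.n_rows, p = X.n_cols, nlam = lambda.n_elem;
  // full-data sufficient statistics for rank-one downdates
  mat XtX = X.t() * X;
  vec Xty = X.t() * y;
  rowvec csum = sum(X, 0);
  const double ysum = accu(y);
  mat errs(n, nlam, fill::zeros);
  ivec iters(nlam);
  const double nl = double(n - 1);
  for (uword i = 0; i < n; ++i) {
    rowvec xi = X.row(i);
    vec m = (csum - xi).t() / nl;                 // fold means
    mat S2 = XtX - xi.t() * xi;                   // fold X'X
    vec s2 = (S2.diag() - nl * square(m)) / nl;   // fold population variances
    s2.elem(find(s2 < 0)).zeros();
    vec s = sqrt(s2);
    vec s_safe = s;
    s_safe.elem(find(s <= 0)).fill(1.0);
    const double my = (ysum - y(i)) / nl;
    // standardised Gram and covariance with centred response
    mat G = (S2 - nl * (m * m.t())) / nl;
    G = G / (s_safe * s_safe.t());
    vec cv = (Xty - xi.t() * y(i) - nl * m * my) / nl;
    cv /= s_safe;
    // dead coordinates (constant in the fold)
    uvec dead = find(s <= 0);
    for (uword k = 0; k < dead.n_elem; ++k) {
      G.row(dead(k)).zeros();
      G.col(dead(k)).zeros();
      cv(dead(k)) = 0;
    }
    iters.zeros();
    mat B = cd_path(G, cv, lambda, tol, maxit, iters);
    vec zi = (xi.t() - m) / s_safe;
    zi.elem(dead).zeros();
    for (uword l = 0; l < nlam; ++l) {
      const double pred = my + dot(zi, B.col(l));
      const double e = y(i) - pred;
      errs(i, l) = e * e;
    }
  }
  return errs;
}
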