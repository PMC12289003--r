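// Blocked Gibbs sampler for the conjugate Gaussian linear model
//   y ~ N(X beta, sigma2 I),  beta_j ~ N(mu0_j, 1/prec0_j),
//   sigma2 ~ InvGamma(shape0, scale0).
// Full conditionals:
//   beta | sigma2 ~ N(mu_n, P^-1),  P = X'X/sigma2 + diag(prec0),
//                   mu_n = P^-1 (X'y/sigma2 + prec0 * mu0)
//   sigma2 | beta ~ InvGamma(shape0 + n/2, scale0 + RSS/2)
// Uses R's RNG so draws are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".gibbs_conjugate_lm")]]
List gibbs_conjugate_lm(const arma::mat& X, const arma::vec& y,
                        const arma::vec& mu0, const arma::vec& prec0,
                        double shape0, double scale0,
                        int n_burn, int n_keep,
                        arma::vec beta, double sigma2,
                        double fixed_sigma2) {
  const int n = X.n_rows, p = X.n_cols;
  const arma::mat XtX = X.t() * X;
  const arma::vec Xty = X.t() * y;
  const arma::vec prior_term = prec0 % mu0;
  const bool sample_sigma = fixed_sigma2 <= 0.0;
  if (!sample_sigma) sigma2 = fixed_sigma2;

  arma::mat beta_draws(n_keep, p);
  arma::vec sigma2_draws(n_keep);

  const int total = n_burn + n_keep;
  for (int it = 0; it < total; ++it) {
    // coefficient block
    arma::mat P = XtX / sigma2;
    P.diag() += prec0;
    arma::mat U = arma::chol(P); // upper: P = U'U
    arma::vec b = Xty / sigma2 + prior_term;
    arma::vec mu = arma::solve(arma::trimatu(U),
                               arma::solve(arma::trimatl(U.t()), b));
    arma::vec zdraw(p);
    for (int j = 0; j < p; ++j) zdraw(j) = R::norm_rand();
    beta = mu + arma::solve(arma::trimatu(U), zdraw);

    // variance block
    if (sample_sigma) {
      arma::vec resid = y - X * beta;
      double rss = arma::dot(resid, resid);
      double shape = shape0 + 0.5 * n;
      double rate = scale0 + 0.5 * rss;
      sigma2 = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    if (it >= n_burn) {
      beta_draws.row(it - n_burn) = beta.t();
      sigma2_draws(it - n_burn) = sigma2;
    }
  }
  return List::create(Named("beta") = beta_draws,
                      Named("sigma2") = sigma2_draws);
}
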