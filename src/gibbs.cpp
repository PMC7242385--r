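#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gibbs sampler for the Gaussian linear model with N(0, tau^2 I) prior on
// the coefficients and a half-Gaussian prior (scale sps) on the residual
// SD. Coefficients are drawn from their exact conjugate conditional; the
// residual scale by univariate slice sampling on log(sigma). Uses R's RNG
// so draws are reproducible under set.seed().

static double logf_sigma(double u, double n, double ssr, double sps2) {
  return (1.0 - n) * u - ssr * std::exp(-2.0 * u) / 2.0 -
         std::exp(2.0 * u) / (2.0 * sps2);
}

static double slice_logsigma(double x0, double n, double ssr, double sps2,
                             double w = 1.0, int max_step = 50) {
  double y = logf_sigma(x0, n, ssr, sps2) + std::log(R::runif(0.0, 1.0));
  double L = x0 - w * R::runif(0.0, 1.0);
  double Rr = L + w;
  int j = (int)std::floor(max_step * R::runif(0.0, 1.0));
  int k = max_step - 1 - j;
  while (j > 0 && y < logf_sigma(L, n, ssr, sps2)) { L -= w; --j; }
  while (k > 0 && y < logf_sigma(Rr, n, ssr, sps2)) { Rr += w; --k; }
  for (;;) {
    double x1 = L + R::runif(0.0, 1.0) * (Rr - L);
    if (y < logf_sigma(x1, n, ssr, sps2)) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
}

// [[Rcpp::export]]
List gibbs_lm_cpp(const arma::mat& XtX, const arma::vec& Xty, double yty,
                  int n, double prior_scale, double sigma_prior_scale,
                  int chains, int iter, const arma::vec& beta_init,
                  double log_sigma_init) {
  const int k = XtX.n_rows;
  const double sps2 = sigma_prior_scale * sigma_prior_scale;
  arma::mat prior_prec = arma::eye(k, k) / (prior_scale * prior_scale);
  arma::mat beta_all(chains * iter, k);
  arma::vec sigma_all(chains * iter);

  for (int ch = 0; ch < chains; ++ch) {
    arma::vec beta(k);
    for (int j = 0; j < k; ++j)
      beta[j] = beta_init[j] + R::rnorm(0.0, 1.0) * 2.0 *
                std::exp(log_sigma_init) / std::sqrt((double)n);
    double u = log_sigma_init + R::runif(-1.0, 1.0);
    for (int it = 0; it < 2 * iter; ++it) {
      double s2 = std::exp(2.0 * u);
      arma::mat prec = XtX / s2 + prior_prec;
      arma::mat Rchol = arma::chol(prec);            // upper triangular
      arma::vec mu = arma::solve(arma::trimatu(Rchol),
                     arma::solve(arma::trimatl(Rchol.t()), Xty / s2));
      arma::vec z(k);
      for (int j = 0; j < k; ++j) z[j] = R::rnorm(0.0, 1.0);
      beta = mu + arma::solve(arma::trimatu(Rchol), z);
      double ssr = yty - 2.0 * arma::dot(beta, Xty) +
                   arma::as_scalar(beta.t() * XtX * beta);
      if (ssr < 0) ssr = 0;
      u = slice_logsigma(u, (double)n, ssr, sps2);
      if (it >= iter) {
        int idx = ch * iter + (it - iter);
        beta_all.row(idx) = beta.t();
        sigma_all[idx] = std::exp(u);
      }
    }
  }
  return List::create(_["beta"] = beta_all, _["sigma"] = sigma_all);
}
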