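#include <Rcpp.h>
using namespace Rcpp;

// Gibbs chain for the two-group fixed-effect linear model
//   y = mu + beta * g + e,  e ~ N(0, sigma2),
// flat priors on (mu, beta) and on sigma2.
//
// Conditionals:
//   (mu, beta) | sigma2, y  ~  joint Normal around the least-squares
//     solution; with a 0/1 group indicator this reduces to
//       mu   = mean1 + z1 * sqrt(sigma2 / n1)
//       beta = (mean2 - mean1) - z1 * sqrt(sigma2/n1) + z2 * sqrt(sigma2/n2)
//     (Cholesky of sigma2 * (X'X)^-1 written out).
//   sigma2 | mu, beta, y ~ InvGamma(shape = n/2, scale = SSE/2), the full
//     conditional under the Jeffreys reference prior 1/sigma2 -- the
//     noninformative choice whose marginal for beta is exactly Student-t
//     with n - 2 degrees of freedom.
//
// Retains floor((iterations - burn_in) / lag) draws; columns mu, beta, sigma2.
// [[Rcpp::export]]
NumericMatrix gibbs_lm_chain(NumericVector y, IntegerVector g,
                             int iterations, int burn_in, int lag,
                             double sigma2_start) {
  int n = y.size();
  if (g.size() != n) stop("y and g lengths differ");
  int n2 = 0;
  double sum1 = 0.0, sum2 = 0.0, ss1 = 0.0, ss2 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (g[i] == 1) { ++n2; sum2 += y[i]; ss2 += y[i] * y[i]; }
    else           { sum1 += y[i]; ss1 += y[i] * y[i]; }
  }
  int n1 = n - n2;
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples");
  if (n < 4) stop("too few residual degrees of freedom");
  double mean1 = sum1 / n1, mean2 = sum2 / n2;
  double shape = n / 2.0;

  int kept = (iterations - burn_in) / lag;
  if (kept < 1) stop("no draws retained: check iterations/burn_in/lag");
  NumericMatrix out(kept, 3);
  colnames(out) = CharacterVector::create("mu", "beta", "sigma2");

  double sigma2 = sigma2_start;
  int row = 0;
  for (int it = 1; it <= iterations; ++it) {
    double s1 = sqrt(sigma2 / n1), s2 = sqrt(sigma2 / n2);
    double z1 = R::norm_rand(), z2 = R::norm_rand();
    double mu = mean1 + z1 * s1;
    double beta = (mean2 - mean1) - z1 * s1 + z2 * s2;
    double m2 = mu + beta;
    double sse = ss1 - 2.0 * mu * sum1 + n1 * mu * mu
               + ss2 - 2.0 * m2 * sum2 + n2 * m2 * m2;
    sigma2 = (sse / 2.0) / R::rgamma(shape, 1.0);
    if (it > burn_in && (it - burn_in) % lag == 0)
      { out(row, 0) = mu; out(row, 1) = beta; out(row, 2) = sigma2; ++row; }
  }
  return out;
}
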