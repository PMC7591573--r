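// Per-pixel CMA-ES minimizer for the quasi-transparency loss.
//
// The objective is the per-pixel cost
//   F(t) = sum_c exp(|L_c . t - I_c|) - C  +  (1/N) sum_n G_n ||t - T_n||^2
// with t box-constrained to [0,1]^w (candidates are clipped before
// evaluation).  The fidelity part receives the quadrature-weighted
// effective-light matrix Lq (C x w) so that Lq * t is the forward integral.
//
// The optimizer is a standard (mu/mu_w, lambda)-CMA-ES with rank-one and
// rank-mu covariance updates.  Randomness comes from an internal splitmix64
// generator so results are reproducible bit-for-bit for a given seed,
// independent of R's RNG state and of the platform's <random> library.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // standard normal via Box-Muller (cached second deviate)
  bool have = false;
  double cached = 0.0;
  double norm() {
    if (have) { have = false; return cached; }
    double u1 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.2831853071795864769 * u2;
    cached = r * std::sin(a);
    have = true;
    return r * std::cos(a);
  }
};

double pixel_cost(const arma::vec& t, const arma::mat& Lq, const arma::vec& obs,
                  const arma::mat& nb, const arma::vec& gw, double invN) {
  arma::vec pred = Lq * t;
  double fid = arma::accu(arma::exp(arma::abs(pred - obs))) -
               static_cast<double>(obs.n_elem);
  double sm = 0.0;
  for (arma::uword j = 0; j < nb.n_cols; ++j) {
    arma::vec d = t - nb.col(j);
    sm += gw(j) * arma::dot(d, d);
  }
  return fid + invN * sm;
}

} // namespace

// [[Rcpp::export(name = ".cma_solve")]]
Rcpp::List cma_solve(arma::vec init, arma::mat Lq, arma::vec obs,
                     arma::mat nb, arma::vec gw,
                     double tol, int budget, double sigma0,
                     int lambda, double seed) {
  const arma::uword n = init.n_elem;
  const double invN = nb.n_cols > 0 ? 1.0 / static_cast<double>(nb.n_cols) : 0.0;

  SplitMix rng(static_cast<uint64_t>(seed));

  arma::vec best_x = arma::clamp(init, 0.0, 1.0);
  double best_f = pixel_cost(best_x, Lq, obs, nb, gw, invN);
  int counteval = 1;
  if (best_f <= tol || budget <= 1) {
    return Rcpp::List::create(Rcpp::Named("par") = best_x,
                              Rcpp::Named("value") = best_f,
                              Rcpp::Named("evals") = counteval,
                              Rcpp::Named("reached") = best_f <= tol);
  }

  if (lambda <= 0)
    lambda = 4 + static_cast<int>(std::floor(3.0 * std::log(static_cast<double>(n))));
  const int mu = lambda / 2;
  arma::vec weights(mu);
  for (int i = 0; i < mu; ++i)
    weights(i) = std::log(mu + 0.5) - std::log(i + 1.0);
  weights /= arma::accu(weights);
  const double mueff = 1.0 / arma::accu(arma::square(weights));

  const double nn = static_cast<double>(n);
  const double cc = (4.0 + mueff / nn) / (nn + 4.0 + 2.0 * mueff / nn);
  const double cs = (mueff + 2.0) / (nn + mueff + 5.0);
  const double c1 = 2.0 / ((nn + 1.3) * (nn + 1.3) + mueff);
  const double cmu = std::min(1.0 - c1,
      2.0 * (mueff - 2.0 + 1.0 / mueff) / ((nn + 2.0) * (nn + 2.0) + mueff));
  const double damps =
      1.0 + 2.0 * std::max(0.0, std::sqrt((mueff - 1.0) / (nn + 1.0)) - 1.0) + cs;
  const double chiN = std::sqrt(nn) * (1.0 - 1.0 / (4.0 * nn) + 1.0 / (21.0 * nn * nn));

  arma::vec xmean = best_x;
  double sigma = sigma0;
  arma::vec pc(n, arma::fill::zeros), ps(n, arma::fill::zeros);
  arma::mat B = arma::eye(n, n);
  arma::vec D(n, arma::fill::ones);
  arma::mat C = arma::eye(n, n);
  arma::mat invsqrtC = arma::eye(n, n);
  int eigeneval = 1;

  arma::mat arx(n, lambda), arz(n, lambda);
  arma::vec arf(lambda);

  while (counteval < budget) {
    int k = 0;
    for (; k < lambda && counteval < budget; ++k) {
      for (arma::uword i = 0; i < n; ++i) arz(i, k) = rng.norm();
      arx.col(k) = arma::clamp(xmean + sigma * (B * (D % arz.col(k))), 0.0, 1.0);
      arf(k) = pixel_cost(arx.col(k), Lq, obs, nb, gw, invN);
      ++counteval;
    }
    if (k < 2) break; // budget exhausted mid-generation

    arma::uvec ord = arma::sort_index(arf.head(k));
    if (arf(ord(0)) < best_f) {
      best_f = arf(ord(0));
      best_x = arx.col(ord(0));
    }
    if (best_f <= tol) break;

    const int muk = std::min(mu, k);
    arma::vec xold = xmean;
    xmean.zeros();
    for (int i = 0; i < muk; ++i) xmean += weights(i) * arx.col(ord(i));

    ps = (1.0 - cs) * ps +
         std::sqrt(cs * (2.0 - cs) * mueff) * (invsqrtC * (xmean - xold)) / sigma;
    const double psn = arma::norm(ps);
    const bool hsig =
        psn / std::sqrt(1.0 - std::pow(1.0 - cs, 2.0 * counteval / lambda)) / chiN <
        1.4 + 2.0 / (nn + 1.0);
    pc = (1.0 - cc) * pc;
    if (hsig) pc += std::sqrt(cc * (2.0 - cc) * mueff) * (xmean - xold) / sigma;

    arma::mat artmp(n, muk);
    for (int i = 0; i < muk; ++i)
      artmp.col(i) = (arx.col(ord(i)) - xold) / sigma;
    C = (1.0 - c1 - cmu) * C +
        c1 * (pc * pc.t() + (hsig ? 0.0 : cc * (2.0 - cc)) * C) +
        cmu * artmp * arma::diagmat(weights.head(muk)) * artmp.t();

    sigma *= std::exp((cs / damps) * (psn / chiN - 1.0));
    if (!std::isfinite(sigma) || sigma < 1e-14 || sigma > 1e6) break;

    if (counteval - eigeneval >
        static_cast<double>(lambda) / (c1 + cmu) / nn / 10.0) {
      eigeneval = counteval;
      C = arma::symmatu(C);
      arma::vec d2;
      if (!arma::eig_sym(d2, B, C)) break;
      D = arma::sqrt(arma::clamp(d2, 1e-20, arma::datum::inf));
      invsqrtC = B * arma::diagmat(1.0 / D) * B.t();
    }
  }

  return Rcpp::List::create(Rcpp::Named("par") = best_x,
                            Rcpp::Named("value") = best_f,
                            Rcpp::Named("evals") = counteval,
                            Rcpp::Named("reached") = best_f <= tol);
}
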