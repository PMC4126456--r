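// Metropolis-Hastings chain over binary regulator configurations.
//
// The state space is the set of 0/1 vectors over n_r candidate regulators
// with fewer than k ones. Proposals are uniform single-bit flips restricted
// to that space; the Hastings correction uses the neighborhood sizes of the
// two endpoints, which differ at the size boundary. Scores are the g-prior
// log marginal plus the configuration log prior; they are memoized per chain
// because small spaces are revisited heavily.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <string>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Scorer {
  const arma::mat &X;      // n_r x n_p centered design rows
  const arma::vec &y;      // centered response
  int k;
  int prior_type;          // 0 flat, 1 sparse (beta-binomial), 2 network
  double pa, pb;           // sparse shapes
  const arma::vec &gamma;  // network prior row weights
  double cond_cap;
  double tss;
  int n_r, n_p;
  long unident = 0;
  std::unordered_map<std::string, double> memo;

  Scorer(const arma::mat &X_, const arma::vec &y_, int k_, int prior_type_,
         double pa_, double pb_, const arma::vec &gamma_, double cond_cap_)
      : X(X_), y(y_), k(k_), prior_type(prior_type_), pa(pa_), pb(pb_),
        gamma(gamma_), cond_cap(cond_cap_) {
    tss = arma::dot(y, y);
    n_r = X.n_rows;
    n_p = X.n_cols;
  }

  double log_prior(const std::vector<int> &bits, int ni) {
    switch (prior_type) {
      case 1:
        return R::lchoose(n_r, ni) + R::lbeta(ni + pa, n_r - ni + pb) -
               R::lbeta(pa, pb);
      case 2: {
        double s = 0.0;
        for (int j = 0; j < n_r; ++j)
          if (bits[j]) s += gamma(j);
        return s;
      }
      default:
        return 0.0;
    }
  }

  double score(const std::vector<int> &bits, int ni) {
    if (ni >= k) return R_NegInf;
    std::string key(bits.begin(), bits.end());
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;

    double r2 = 0.0;
    if (ni > 0) {
      arma::uvec sel(ni);
      int m = 0;
      for (int j = 0; j < n_r; ++j)
        if (bits[j]) sel(m++) = j;
      arma::mat Xs = X.rows(sel);
      arma::mat gram = Xs * Xs.t();
      double rc = arma::rcond(gram);
      if (!std::isfinite(rc) || rc < 1.0 / cond_cap) {
        ++unident;
        memo.emplace(key, R_NegInf);
        return R_NegInf;
      }
      arma::vec beta = arma::solve(gram, Xs * y, arma::solve_opts::likely_sympd);
      arma::vec resid = y - Xs.t() * beta;
      r2 = 1.0 - arma::dot(resid, resid) / tss;
      if (r2 < 0.0) r2 = 0.0;
      if (r2 > 1.0) r2 = 1.0;
    }
    double c = std::max(static_cast<double>(n_p),
                        static_cast<double>(ni) * ni);
    double lm = -((ni + 1) / 2.0) * std::log1p(c) -
                ((n_p - 1) / 2.0) * std::log(1.0 - (c / (1.0 + c)) * r2);
    double s = lm + log_prior(bits, ni);
    memo.emplace(key, s);
    return s;
  }
};

}  // namespace

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(const arma::mat &X, const arma::vec &y, int k,
                   int iterations, int burn_in, int thinning, int prior_type,
                   double pa, double pb, const arma::vec &gamma_row,
                   double cond_cap) {
  const int n_r = X.n_rows;
  if (k < 2) stop("restriction parameter k must be at least 2 for sampling");
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations");

  Scorer scorer(X, y, k, prior_type, pa, pb, gamma_row, cond_cap);

  // sparse-biased random start, resampled until inside the restricted space
  std::vector<int> bits(n_r, 0);
  double p0 = std::min(0.5, (k - 1) / (2.0 * n_r));
  int ni;
  do {
    ni = 0;
    for (int j = 0; j < n_r; ++j) {
      bits[j] = (unif_rand() < p0) ? 1 : 0;
      ni += bits[j];
    }
  } while (ni >= k);

  double cur = scorer.score(bits, ni);

  const int n_keep = iterations - burn_in;
  const int n_s = (n_keep + thinning - 1) / thinning;
  IntegerMatrix samples(n_s, n_r);
  NumericVector score_trace(n_s);
  long accepted = 0;
  int row = 0;

  for (int t = 1; t <= iterations; ++t) {
    // propose a uniform single-bit flip within the restricted space
    int fwd, rev, flip;
    if (ni <= k - 2) {
      fwd = n_r;
      flip = static_cast<int>(unif_rand() * n_r);
      if (flip == n_r) flip = n_r - 1;
    } else {  // ni == k - 1: additions blocked, removals only
      fwd = ni;
      int which = static_cast<int>(unif_rand() * ni);
      if (which == ni) which = ni - 1;
      flip = -1;
      for (int j = 0, seen = 0; j < n_r; ++j) {
        if (bits[j] && seen++ == which) { flip = j; break; }
      }
    }
    int ni_new = ni + (bits[flip] ? -1 : 1);
    rev = (ni_new <= k - 2) ? n_r : ni_new;

    bits[flip] ^= 1;
    double prop = scorer.score(bits, ni_new);
    bool accept = false;
    if (R_finite(prop) || prop > R_NegInf) {
      if (prop > R_NegInf) {
        double log_alpha = prop - cur + std::log(static_cast<double>(fwd)) -
                           std::log(static_cast<double>(rev));
        accept = (log_alpha >= 0.0) || (unif_rand() < std::exp(log_alpha));
      }
    }
    if (accept) {
      cur = prop;
      ni = ni_new;
      ++accepted;
    } else {
      bits[flip] ^= 1;  // revert
    }

    if (t > burn_in && ((t - burn_in - 1) % thinning == 0)) {
      for (int j = 0; j < n_r; ++j) samples(row, j) = bits[j];
      score_trace[row] = cur;
      ++row;
    }
  }

  return List::create(
      Named("samples") = samples,
      Named("score_trace") = score_trace,
      Named("accept_count") = static_cast<double>(accepted),
      Named("n_s") = n_s,
      Named("unidentifiable_count") = static_cast<double>(scorer.unident));
}
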