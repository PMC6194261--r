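// Core numerics for the open-population N-mixture likelihood.
//
// Latent abundance N_it lives on the truncated grid 0..K. Between primary
// periods, survivors are Binomial(N_{t-1}, omega) and recruits Poisson with
// rate gamma (constant dynamics) or gamma * N_{t-1} (autoregressive); the
// state K absorbs all truncated upper-tail mass so kernel rows sum to 1.
// The filter runs in scaled probability space with a log accumulator, which
// is algebraically the log-space recursion but avoids K^2 log-sum-exp calls.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat kernel(double omega, double gamma, int dynamics, int K) {
  arma::mat Q(K + 1, K + 1, arma::fill::zeros);
  std::vector<double> brow(K + 1, 0.0), bprev(K + 1, 0.0),
      pois(K + 1, 0.0), utail(K + 1, 0.0);
  // Poisson pmf by the ratio recurrence (fallback to R::dpois when
  // exp(-rate) underflows) plus the upper tail P(X >= m), anchored by one
  // accurate ppois call and filled downward by positive additions -- the
  // absorbed tail mass must never be formed as 1 minus a row sum, which
  // cancels catastrophically when the tail is small.
  auto fill_pois = [&](double rate) {
    double p0 = std::exp(-rate);
    if (p0 > 0.0) {
      pois[0] = p0;
      for (int r = 1; r <= K; ++r) pois[r] = pois[r - 1] * rate / r;
    } else {
      for (int r = 0; r <= K; ++r) pois[r] = R::dpois(r, rate, 0);
    }
    utail[K] = K > 0 ? R::ppois(K - 1, rate, 0, 0) : 1.0;
    for (int m = K - 1; m >= 0; --m) utail[m] = utail[m + 1] + pois[m];
  };
  if (dynamics == 0) fill_pois(gamma);
  bprev[0] = 1.0;
  for (int a = 0; a <= K; ++a) {
    if (a == 0) {
      brow[0] = 1.0;
    } else {
      // Pascal-style recurrence: dbinom(s; a, w) from the a-1 row
      brow[a] = omega * bprev[a - 1];
      for (int s = a - 1; s >= 1; --s)
        brow[s] = omega * bprev[s - 1] + (1.0 - omega) * bprev[s];
      brow[0] = (1.0 - omega) * bprev[0];
    }
    if (dynamics == 1) fill_pois(gamma * a);
    for (int b = 0; b < K; ++b) {
      double acc = 0.0;
      int smax = std::min(a, b);
      for (int s = 0; s <= smax; ++s) acc += brow[s] * pois[b - s];
      Q(a, b) = acc;
    }
    double tail = 0.0; // survivors s plus >= K - s recruits overflow into K
    for (int s = 0; s <= std::min(a, K); ++s) tail += brow[s] * utail[K - s];
    Q(a, K) = tail;
    bprev = brow;
  }
  return Q;
}

// [[Rcpp::export]]
arma::mat trans_kernel_cpp(double omega, double gamma, int dynamics, int K) {
  return kernel(omega, gamma, dynamics, K);
}

// Per-visit binomial log-likelihood accumulated onto the state grid.
// y, site, year are parallel vectors over non-missing visits (0-based
// site/year); lchoose_tab[n, k] = log choose(n, k), (K+1) x (K+1).
// Returns cube (K+1) x T x M of log P(all visits in (i,t) | N = n).
// [[Rcpp::export]]
arma::cube detection_logdet_cpp(const arma::ivec& y, const arma::ivec& site,
                                const arma::ivec& year, const arma::vec& p,
                                const arma::mat& lchoose_tab,
                                int M, int T, int K) {
  arma::cube ld(K + 1, T, M, arma::fill::zeros);
  const double neg_inf = -arma::datum::inf;
  for (arma::uword v = 0; v < y.n_elem; ++v) {
    int yv = y[v], i = site[v], t = year[v];
    double lp = std::log(p[v]), lq = std::log1p(-p[v]);
    for (int n = 0; n <= K; ++n) {
      if (n < yv) {
        ld(n, t, i) = neg_inf;
      } else if (ld(n, t, i) > neg_inf) {
        // dbinom(yv; n, p) in log form via the precomputed lchoose table
        ld(n, t, i) += lchoose_tab(n, yv) + yv * lp + (n - yv) * lq;
      }
    }
  }
  return ld;
}

typedef std::map<std::pair<double, double>, arma::mat> KernelCache;

static const arma::mat& cached_kernel(KernelCache& cache, double omega,
                                      double gamma, int dynamics, int K) {
  std::pair<double, double> key(omega, gamma);
  KernelCache::iterator it = cache.find(key);
  if (it == cache.end())
    it = cache.insert(std::make_pair(key, kernel(omega, gamma, dynamics, K))).first;
  return it->second;
}

// Forward (filtering) pass; returns per-site log-likelihoods.
// log_init: M x (K+1); log_det: (K+1) x T x M; omega/gamma: M x (T-1).
// [[Rcpp::export]]
arma::vec forward_loglik_cpp(const arma::mat& log_init, const arma::cube& log_det,
                             const arma::mat& omega, const arma::mat& gamma,
                             int dynamics, int K) {
  const int M = log_init.n_rows, T = log_det.n_cols;
  arma::vec ll(M);
  KernelCache cache;
  for (int i = 0; i < M; ++i) {
    arma::rowvec work = log_init.row(i) + log_det.slice(i).col(0).t();
    double m = work.max();
    if (!std::isfinite(m)) { ll[i] = -arma::datum::inf; continue; }
    arma::rowvec alpha = arma::exp(work - m);
    double logc = m + std::log(arma::accu(alpha));
    alpha /= arma::accu(alpha);
    bool dead = false;
    for (int t = 1; t < T; ++t) {
      const arma::mat& Q = cached_kernel(cache, omega(i, t - 1), gamma(i, t - 1),
                                         dynamics, K);
      alpha = alpha * Q;
      arma::rowvec ld = log_det.slice(i).col(t).t();
      double md = ld.max();
      if (!std::isfinite(md)) { dead = true; break; }
      alpha %= arma::exp(ld - md);
      double c = arma::accu(alpha);
      if (!(c > 0.0) || !std::isfinite(c)) { dead = true; break; }
      logc += md + std::log(c);
      alpha /= c;
    }
    ll[i] = dead ? -arma::datum::inf : logc;
  }
  return ll;
}

// Forward-backward smoother: posterior P(N_it = n | all counts at site i)
// evaluated at the supplied parameters. Returns cube (K+1) x T x M.
// [[Rcpp::export]]
arma::cube forward_backward_cpp(const arma::mat& log_init, const arma::cube& log_det,
                                const arma::mat& omega, const arma::mat& gamma,
                                int dynamics, int K) {
  const int M = log_init.n_rows, T = log_det.n_cols;
  arma::cube post(K + 1, T, M, arma::fill::zeros);
  KernelCache cache;
  for (int i = 0; i < M; ++i) {
    arma::mat fwd(K + 1, T);            // scaled filtered densities
    arma::rowvec work = log_init.row(i) + log_det.slice(i).col(0).t();
    double m = work.max();
    arma::rowvec alpha = arma::exp(work - m);
    alpha /= arma::accu(alpha);
    fwd.col(0) = alpha.t();
    for (int t = 1; t < T; ++t) {
      const arma::mat& Q = cached_kernel(cache, omega(i, t - 1), gamma(i, t - 1),
                                         dynamics, K);
      alpha = alpha * Q;
      arma::rowvec ld = log_det.slice(i).col(t).t();
      alpha %= arma::exp(ld - ld.max());
      double c = arma::accu(alpha);
      if (!(c > 0.0)) c = 1.0;          // impossible data; posterior undefined
      alpha /= c;
      fwd.col(t) = alpha.t();
    }
    arma::vec beta(K + 1, arma::fill::ones);
    for (int t = T - 1; t >= 0; --t) {
      arma::vec u = fwd.col(t) % beta;
      double s = arma::accu(u);
      post.slice(i).col(t) = s > 0 ? u / s : u;
      if (t > 0) {
        const arma::mat& Q = cached_kernel(cache, omega(i, t - 1), gamma(i, t - 1),
                                           dynamics, K);
        arma::rowvec ld = log_det.slice(i).col(t).t();
        arma::vec emis = arma::exp(ld - ld.max()).t();
        beta = Q * (emis % beta);
        double bs = arma::accu(beta);
        if (bs > 0) beta /= bs;         // rescale; posterior is normalized anyway
      }
    }
  }
  return post;
}
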