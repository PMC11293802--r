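// Metropolis-within-Gibbs cores for the BGWR hierarchical model.
// All randomness goes through R's RNG so set.seed() in R governs the draws.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double WEIGHT_FLOOR = 1e-12; // keeps bounded-support kernels nonsingular

// kernel_id: 0 exponential, 1 gaussian, 2 bisquare
static inline double kernel_w(double d, double b, int kernel_id) {
  switch (kernel_id) {
    case 0: return std::exp(-d / b);
    case 1: return std::exp(-(d / b) * (d / b));
    default: {
      if (d >= b) return 0.0;
      double u = 1.0 - (d / b) * (d / b);
      return u * u;
    }
  }
}

// n x S weight matrix: w(i, s) = f(d(region_i, s) | b), floored.
static arma::mat weight_matrix(const arma::mat& D, const arma::uvec& region,
                               double b, int kernel_id) {
  const arma::uword S = D.n_cols, n = region.n_elem;
  arma::mat Wreg(S, S);
  for (arma::uword s = 0; s < S; ++s)
    for (arma::uword r = 0; r < S; ++r)
      Wreg(r, s) = std::max(kernel_w(D(r, s), b, kernel_id), WEIGHT_FLOOR);
  arma::mat W(n, S);
  for (arma::uword i = 0; i < n; ++i) W.row(i) = Wreg.row(region(i));
  return W;
}

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// Joint weighted pseudo-log-likelihood over all focal regions, up to
// constants shared between bandwidth proposals with fixed beta/sigma2:
// sum_s sum_i [ 0.5*log w_i(s) - w_i(s) r_i(s)^2 / (2 sigma2(s)) ].
static double bandwidth_loglik(const arma::mat& W, const arma::mat& R2,
                               const arma::vec& sigma2) {
  double ll = 0.0;
  for (arma::uword s = 0; s < W.n_cols; ++s) {
    ll += 0.5 * arma::accu(arma::log(W.col(s)));
    ll -= arma::dot(W.col(s), R2.col(s)) / (2.0 * sigma2(s));
  }
  return ll;
}

// Draw beta(s) for all regions from the conjugate MVN full conditionals,
// restricted to the included columns of each region. Beta is S x p.
static void gibbs_beta(arma::mat& Beta, const arma::vec& y, const arma::mat& X,
                       const arma::mat& W, const arma::umat& incl,
                       const arma::vec& sigma2, double sigma_beta2) {
  const arma::uword S = W.n_cols;
  for (arma::uword s = 0; s < S; ++s) {
    arma::uvec idx = arma::find(incl.row(s).t() == 1);
    if (idx.n_elem == 0) continue;
    arma::mat Xa = X.cols(idx);
    arma::vec ws = W.col(s);
    arma::mat Xw = Xa.each_col() % ws;                    // n x pa
    arma::mat A = Xa.t() * Xw / sigma2(s);                // pa x pa
    A.diag() += 1.0 / sigma_beta2;
    arma::vec bv = Xw.t() * y / sigma2(s);
    arma::mat L = arma::chol(A, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), bv));
    arma::vec z(idx.n_elem);
    for (arma::uword k = 0; k < z.n_elem; ++k) z(k) = R::norm_rand();
    arma::vec draw = mu + arma::solve(arma::trimatu(L.t()), z);
    Beta.row(s).zeros();
    for (arma::uword k = 0; k < idx.n_elem; ++k) Beta(s, idx(k)) = draw(k);
  }
}

static inline double reflect_into(double x, double lo, double hi) {
  // reflect a random-walk proposal into (lo, hi)
  double span = hi - lo;
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  (void)span;
  return x;
}

// [[Rcpp::export]]
List cpp_bgwr_mcmc(const arma::vec& y, const arma::mat& X,
                   const arma::uvec& region, const arma::mat& D,
                   const arma::umat& active, int kernel_id,
                   bool estimate_b, double b_init, double Dmax, double b_step,
                   double ll_scale,
                   double alpha1, double alpha2, double a_beta, double b_beta,
                   int n_iter, int burn_in, int thin) {
  const arma::uword n = y.n_elem, S = D.n_cols, p = X.n_cols;
  const double n_total_active = arma::accu(active);

  arma::mat Beta(S, p, arma::fill::zeros);
  arma::vec sigma2(S, arma::fill::ones);
  double sigma_beta2 = 1.0;
  double b = b_init;
  arma::mat W = weight_matrix(D, region, b, kernel_id);

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  arma::cube beta_draws(S, p, n_keep);
  arma::mat sigma2_draws(n_keep, S);
  arma::vec sb2_draws(n_keep), b_draws(n_keep);
  int kept = 0, b_prop = 0, b_acc = 0;

  for (int it = 0; it < n_iter; ++it) {
    gibbs_beta(Beta, y, X, W, active, sigma2, sigma_beta2);

    // sigma2(s) | rest ~ InvGamma(alpha1 + n/2, alpha2 + 0.5 * sum w r^2)
    arma::mat R = arma::repmat(y, 1, S) - X * Beta.t();   // n x S residuals
    arma::mat R2 = R % R;
    for (arma::uword s = 0; s < S; ++s) {
      double rate = alpha2 + 0.5 * arma::dot(W.col(s), R2.col(s));
      sigma2(s) = rinvgamma(alpha1 + 0.5 * n, rate);
    }

    // shared sigma_beta2 | rest
    double ssq = 0.0;
    for (arma::uword s = 0; s < S; ++s)
      for (arma::uword j = 0; j < p; ++j)
        if (active(s, j)) ssq += Beta(s, j) * Beta(s, j);
    sigma_beta2 = rinvgamma(a_beta + 0.5 * n_total_active, b_beta + 0.5 * ssq);

    // shared bandwidth: reflected random-walk Metropolis on (0, Dmax)
    if (estimate_b) {
      ++b_prop;
      double b_new = reflect_into(b + b_step * R::norm_rand(), 0.0, Dmax);
      arma::mat W_new = weight_matrix(D, region, b_new, kernel_id);
      double ll_old = bandwidth_loglik(W, R2, sigma2);
      double ll_new = bandwidth_loglik(W_new, R2, sigma2);
      if (!std::isfinite(ll_new) || !std::isfinite(ll_old))
        stop("non-finite bandwidth log-likelihood at iteration %d", it + 1);
      if (std::log(R::unif_rand()) < ll_scale * (ll_new - ll_old)) {
        b = b_new;
        W = W_new;
        ++b_acc;
      }
    }

    if (!Beta.is_finite() || !sigma2.is_finite())
      stop("divergent sampler state at iteration %d", it + 1);

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      beta_draws.slice(kept) = Beta;
      sigma2_draws.row(kept) = sigma2.t();
      sb2_draws(kept) = sigma_beta2;
      b_draws(kept) = b;
      ++kept;
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["sigma2"] = sigma2_draws,
    _["sigma_beta2"] = sb2_draws, _["bandwidth"] = b_draws,
    _["accept_rate"] = b_prop > 0 ? (double)b_acc / b_prop : NA_REAL,
    _["n_kept"] = kept);
}

// [[Rcpp::export]]
List cpp_bgwr_select_mcmc(const arma::vec& y, const arma::mat& X,
                          const arma::uvec& region, const arma::mat& D,
                          const arma::umat& active,
                          const arma::uvec& always_include, int kernel_id,
                          bool estimate_b, double b_init, double Dmax,
                          double b_step, double ll_scale,
                          double alpha1, double alpha2,
                          double a_beta, double b_beta,
                          int n_iter, int burn_in, int thin) {
  const arma::uword n = y.n_elem, S = D.n_cols, p = X.n_cols;

  arma::mat Beta(S, p, arma::fill::zeros);
  arma::umat gamma = active;                 // start with everything in
  arma::vec psi(p, arma::fill::value(0.5));
  arma::vec sigma2(S, arma::fill::ones);
  double sigma_beta2 = 1.0;
  double b = b_init;
  arma::mat W = weight_matrix(D, region, b, kernel_id);

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  arma::cube beta_draws(S, p, n_keep);
  arma::ucube gamma_draws(S, p, n_keep);
  arma::mat sigma2_draws(n_keep, S), psi_draws(n_keep, p);
  arma::vec sb2_draws(n_keep), b_draws(n_keep);
  int kept = 0, b_prop = 0, b_acc = 0;

  for (int it = 0; it < n_iter; ++it) {
    // include = gamma AND active mask (gamma is kept 0 where masked out)
    gibbs_beta(Beta, y, X, W, gamma, sigma2, sigma_beta2);

    arma::mat R = arma::repmat(y, 1, S) - X * Beta.t();
    arma::mat R2 = R % R;
    for (arma::uword s = 0; s < S; ++s) {
      double rate = alpha2 + 0.5 * arma::dot(W.col(s), R2.col(s));
      sigma2(s) = rinvgamma(alpha1 + 0.5 * n, rate);
    }

    double ssq = arma::accu(Beta % Beta);
    sigma_beta2 = rinvgamma(a_beta + 0.5 * arma::accu(gamma),
                            b_beta + 0.5 * ssq);

    if (estimate_b) {
      ++b_prop;
      double b_new = reflect_into(b + b_step * R::norm_rand(), 0.0, Dmax);
      arma::mat W_new = weight_matrix(D, region, b_new, kernel_id);
      double ll_old = bandwidth_loglik(W, R2, sigma2);
      double ll_new = bandwidth_loglik(W_new, R2, sigma2);
      if (!std::isfinite(ll_new) || !std::isfinite(ll_old))
        stop("non-finite bandwidth log-likelihood at iteration %d", it + 1);
      if (std::log(R::unif_rand()) < ll_scale * (ll_new - ll_old)) {
        b = b_new;
        W = W_new;
        ++b_acc;
      }
    }

    // reversible-jump birth/death flips, prior N(0, sigma_beta2) as proposal:
    // proposal and Jacobian cancel, leaving likelihood ratio * psi odds.
    for (arma::uword s = 0; s < S; ++s) {
      arma::vec r = y - X * Beta.row(s).t();   // current residuals, region s
      const double inv2s2 = 1.0 / (2.0 * sigma2(s));
      for (arma::uword j = 0; j < p; ++j) {
        if (always_include(j) || !active(s, j)) continue;
        const arma::vec& ws = W.col(s);
        if (gamma(s, j) == 0) {                // birth
          double bj = R::norm_rand() * std::sqrt(sigma_beta2);
          arma::vec r_new = r - X.col(j) * bj;
          double dll = (arma::dot(ws, r % r) - arma::dot(ws, r_new % r_new)) * inv2s2;
          double log_acc = dll + std::log(psi(j)) - std::log1p(-psi(j));
          if (std::log(R::unif_rand()) < log_acc) {
            gamma(s, j) = 1;
            Beta(s, j) = bj;
            r = r_new;
          }
        } else {                               // death
          arma::vec r_new = r + X.col(j) * Beta(s, j);
          double dll = (arma::dot(ws, r % r) - arma::dot(ws, r_new % r_new)) * inv2s2;
          double log_acc = dll + std::log1p(-psi(j)) - std::log(psi(j));
          if (std::log(R::unif_rand()) < log_acc) {
            gamma(s, j) = 0;
            Beta(s, j) = 0.0;
            r = r_new;
          }
        }
      }
    }

    // psi_j | gamma ~ Beta(1 + sum_s gamma, 1 + S_sel - sum_s gamma),
    // counting only regions where j is selectable
    for (arma::uword j = 0; j < p; ++j) {
      if (always_include(j)) continue;
      double cnt = 0, tot = 0;
      for (arma::uword s = 0; s < S; ++s) {
        if (!active(s, j)) continue;
        tot += 1.0;
        cnt += gamma(s, j);
      }
      psi(j) = R::rbeta(1.0 + cnt, 1.0 + tot - cnt);
      psi(j) = std::min(std::max(psi(j), 1e-12), 1.0 - 1e-12);
    }

    if (!Beta.is_finite() || !sigma2.is_finite())
      stop("divergent sampler state at iteration %d", it + 1);

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      beta_draws.slice(kept) = Beta;
      gamma_draws.slice(kept) = gamma;
      sigma2_draws.row(kept) = sigma2.t();
      psi_draws.row(kept) = psi.t();
      sb2_draws(kept) = sigma_beta2;
      b_draws(kept) = b;
      ++kept;
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["gamma"] = gamma_draws,
    _["sigma2"] = sigma2_draws, _["psi"] = psi_draws,
    _["sigma_beta2"] = sb2_draws, _["bandwidth"] = b_draws,
    _["accept_rate"] = b_prop > 0 ? (double)b_acc / b_prop : NA_REAL,
    _["n_kept"] = kept);
}

// Blocked Gibbs for a truncated stick-breaking DPMM with an independent
// Normal-Inverse-Gamma base per dimension.
// [[Rcpp::export]]
List cpp_dpmm_gibbs(const arma::mat& Y, int H, double alpha,
                    const arma::vec& m0, double kappa0, double a0,
                    const arma::vec& b0, int n_iter, int burn_in) {
  const arma::uword S = Y.n_rows, p = Y.n_cols;
  const arma::uword Hu = (arma::uword)H;

  arma::mat mu(Hu, p), s2(Hu, p, arma::fill::ones);
  for (arma::uword k = 0; k < Hu; ++k) mu.row(k) = m0.t();
  arma::uvec z(S);
  for (arma::uword i = 0; i < S; ++i)
    z(i) = (arma::uword)(R::unif_rand() * Hu) % Hu;
  arma::vec V(Hu), C(Hu);

  const int n_keep = n_iter - burn_in;
  arma::umat z_draws(n_keep, S);
  arma::mat V_draws(n_keep, Hu), C_draws(n_keep, Hu);
  int kept = 0;
  bool saturated = false;

  for (int it = 0; it < n_iter; ++it) {
    // component parameters | z  (conjugate per-dimension NIG updates)
    for (arma::uword k = 0; k < Hu; ++k) {
      arma::uvec idx = arma::find(z == k);
      double nk = (double)idx.n_elem;
      for (arma::uword d = 0; d < p; ++d) {
        double ybar = 0.0, ssd = 0.0;
        if (nk > 0) {
          arma::vec yk = Y(idx, arma::uvec{d});
          ybar = arma::mean(yk);
          ssd = arma::accu(arma::square(yk - ybar));
        }
        double kn = kappa0 + nk;
        double mn = (kappa0 * m0(d) + nk * ybar) / kn;
        double an = a0 + 0.5 * nk;
        double bn = b0(d) + 0.5 * ssd +
          0.5 * kappa0 * nk * (ybar - m0(d)) * (ybar - m0(d)) / kn;
        s2(k, d) = rinvgamma(an, bn);
        mu(k, d) = mn + R::norm_rand() * std::sqrt(s2(k, d) / kn);
      }
    }

    // stick fractions | z: V_k ~ Beta(1 + n_k, alpha + sum_{l>k} n_l)
    arma::vec nk(Hu, arma::fill::zeros);
    for (arma::uword i = 0; i < S; ++i) nk(z(i)) += 1.0;
    double tail = arma::accu(nk);
    double stick = 1.0;
    for (arma::uword k = 0; k < Hu; ++k) {
      tail -= nk(k);
      double v = R::rbeta(1.0 + nk(k), alpha + tail);
      v = std::min(std::max(v, 1e-12), 1.0 - 1e-12);
      V(k) = v;
      C(k) = v * stick;
      stick *= (1.0 - v);
    }

    // assignments | C, theta
    arma::vec logC = arma::log(C);
    for (arma::uword i = 0; i < S; ++i) {
      arma::vec lp = logC;
      for (arma::uword k = 0; k < Hu; ++k) {
        double acc = 0.0;
        for (arma::uword d = 0; d < p; ++d) {
          double rdev = Y(i, d) - mu(k, d);
          acc += -0.5 * std::log(2.0 * M_PI * s2(k, d)) -
                 rdev * rdev / (2.0 * s2(k, d));
        }
        lp(k) += acc;
      }
      lp -= lp.max();
      arma::vec pr = arma::exp(lp);
      pr /= arma::accu(pr);
      double u = R::unif_rand(), cum = 0.0;
      arma::uword pick = Hu - 1;
      for (arma::uword k = 0; k < Hu; ++k) {
        cum += pr(k);
        if (u <= cum) { pick = k; break; }
      }
      z(i) = pick;
    }

    if (it >= burn_in) {
      z_draws.row(kept) = z.t() + 1;   // 1-based labels
      V_draws.row(kept) = V.t();
      C_draws.row(kept) = C.t();
      arma::uvec occ = arma::unique(z);
      if (occ.n_elem == Hu) saturated = true;
      ++kept;
    }
  }

  return List::create(_["z"] = z_draws, _["V"] = V_draws, _["C"] = C_draws,
                      _["saturated"] = saturated);
}
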