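// Gibbs sampler for the window-level mixed-effect logistic model
//
//   m_ij ~ Binomial(c_ij, p_ij),  logit(p_ij) = mu_{g(i)} + x_i'beta
//                                              + v0_i + v1_ij
//   v0_i  ~ N(0, sigma0^2)            (between-individual, within-site)
//   v1_i. ~ N_m(0, Sigma)             (between-site correlation)
//   mu_k  ~ N(0, mu_prior_sd^2)  or hierarchical N(mu_mu, sigma_mu^2)
//   sigma0^2 ~ IG(ig_shape, ig_scale),  Sigma^{-1} ~ Wishart(I_m, m)
//
// Conditionals are conjugate after Polya-Gamma augmentation
// omega_ij ~ PG(c_ij, psi_ij); cells with c_ij = 0 contribute nothing.
// Uses R's RNG throughout so results are reproducible via set.seed().

#include <RcppArmadillo.h>
#include "polyagamma.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvgamma(double shape, double scale) {
  return scale / R::rgamma(shape, 1.0);
}

// Wishart(scale S, df) via Bartlett decomposition; returns a draw.
static arma::mat rwishart(const arma::mat &S, double df) {
  int m = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(m, m, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// [[Rcpp::export(name = ".bfm_gibbs")]]
List bfm_gibbs(const arma::imat &meth, const arma::imat &cov,
               const arma::ivec &group, int K,
               int n_iter, int n_burnin, int thin,
               double mu_prior_sd, double ig_shape, double ig_scale,
               bool hierarchical_mu, bool random_effects,
               const arma::mat &X, double beta_prior_sd,
               int pg_exact_max) {
  const int N = meth.n_rows, m = meth.n_cols;
  const int p = X.n_cols;  // 0 columns = no covariates
  const double mu_prior_prec = 1.0 / (mu_prior_sd * mu_prior_sd);

  arma::mat kappa(N, m);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < m; ++j)
      kappa(i, j) = meth(i, j) - 0.5 * cov(i, j);

  // initialise mu at the empirical pooled logit per group (clamped)
  arma::vec mu(K, arma::fill::zeros);
  {
    arma::vec msum(K, arma::fill::zeros), csum(K, arma::fill::zeros);
    for (int i = 0; i < N; ++i) {
      int k = group(i) - 1;
      msum(k) += arma::accu(meth.row(i));
      csum(k) += arma::accu(cov.row(i));
    }
    for (int k = 0; k < K; ++k) {
      double r = (msum(k) + 0.5) / (csum(k) + 1.0);
      r = std::min(std::max(r, 1e-3), 1.0 - 1e-3);
      mu(k) = std::log(r / (1.0 - r));
    }
  }

  arma::vec v0(N, arma::fill::zeros);
  arma::mat v1(N, m, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  double sigma0_sq = 1.0;
  double mu_mu = 0.0, sigma_mu_sq = 1.0;
  arma::mat SigmaInv = arma::eye(m, m);

  const int S = (n_iter - n_burnin) / thin;
  arma::mat mu_store(S, K);
  arma::mat beta_store(S, std::max(p, 1));
  arma::vec sigma0_store(S, arma::fill::zeros);
  arma::mat omega(N, m, arma::fill::zeros);
  arma::vec xb(N, arma::fill::zeros);

  int s_out = 0;
  for (int it = 0; it < n_iter; ++it) {
    if (p > 0) xb = X * beta;

    // --- omega | rest
    for (int i = 0; i < N; ++i) {
      int k = group(i) - 1;
      for (int j = 0; j < m; ++j) {
        if (cov(i, j) > 0) {
          double psi = mu(k) + xb(i) + v0(i) + v1(i, j);
          omega(i, j) = rpg(cov(i, j), psi, pg_exact_max);
        } else {
          omega(i, j) = 0.0;
        }
      }
    }

    // --- mu_k | rest
    {
      arma::vec prec(K, arma::fill::value(
          hierarchical_mu ? 1.0 / sigma_mu_sq : mu_prior_prec));
      arma::vec num(K, arma::fill::value(
          hierarchical_mu ? mu_mu / sigma_mu_sq : 0.0));
      for (int i = 0; i < N; ++i) {
        int k = group(i) - 1;
        for (int j = 0; j < m; ++j) {
          if (cov(i, j) == 0) continue;
          prec(k) += omega(i, j);
          num(k) += kappa(i, j) - omega(i, j) * (xb(i) + v0(i) + v1(i, j));
        }
      }
      for (int k = 0; k < K; ++k)
        mu(k) = num(k) / prec(k) + norm_rand() / std::sqrt(prec(k));
    }

    if (hierarchical_mu) {
      // mu_mu | mu, sigma_mu^2 with N(0, mu_prior_sd^2) hyperprior
      double prec = mu_prior_prec + K / sigma_mu_sq;
      double num = arma::accu(mu) / sigma_mu_sq;
      mu_mu = num / prec + norm_rand() / std::sqrt(prec);
      double ss = arma::accu(arma::square(mu - mu_mu));
      sigma_mu_sq = rinvgamma(ig_shape + 0.5 * K, ig_scale + 0.5 * ss);
    }

    // --- beta | rest (optional fixed-effect covariates)
    if (p > 0) {
      arma::mat P = arma::eye(p, p) / (beta_prior_sd * beta_prior_sd);
      arma::vec b(p, arma::fill::zeros);
      for (int i = 0; i < N; ++i) {
        int k = group(i) - 1;
        double wsum = 0.0, rsum = 0.0;
        for (int j = 0; j < m; ++j) {
          if (cov(i, j) == 0) continue;
          wsum += omega(i, j);
          rsum += kappa(i, j) - omega(i, j) * (mu(k) + v0(i) + v1(i, j));
        }
        P += wsum * (X.row(i).t() * X.row(i));
        b += rsum * X.row(i).t();
      }
      arma::mat L = arma::chol(P, "lower");
      arma::vec zr(p);
      for (int d = 0; d < p; ++d) zr(d) = norm_rand();
      arma::vec mean = arma::solve(arma::trimatu(L.t()),
                                   arma::solve(arma::trimatl(L), b));
      beta = mean + arma::solve(arma::trimatu(L.t()), zr);
    }

    if (random_effects) {
      // --- v0_i | rest
      for (int i = 0; i < N; ++i) {
        int k = group(i) - 1;
        double prec = 1.0 / sigma0_sq, num = 0.0;
        for (int j = 0; j < m; ++j) {
          if (cov(i, j) == 0) continue;
          prec += omega(i, j);
          num += kappa(i, j) - omega(i, j) * (mu(k) + xb(i) + v1(i, j));
        }
        v0(i) = num / prec + norm_rand() / std::sqrt(prec);
      }

      // --- v1_i | rest (m-variate normal per individual); manual
      // Cholesky on preallocated buffers: this loop dominates runtime.
      {
        arma::mat P(m, m);
        arma::vec b(m), w(m), zr(m);
        for (int i = 0; i < N; ++i) {
          int k = group(i) - 1;
          P = SigmaInv;
          for (int j = 0; j < m; ++j) {
            if (cov(i, j) > 0) {
              P(j, j) += omega(i, j);
              b(j) = kappa(i, j) - omega(i, j) * (mu(k) + xb(i) + v0(i));
            } else {
              b(j) = 0.0;
            }
          }
          // in-place lower Cholesky of P
          for (int c = 0; c < m; ++c) {
            double d = P(c, c);
            for (int r2 = 0; r2 < c; ++r2) d -= P(c, r2) * P(c, r2);
            if (d <= 0.0) stop("non-positive-definite conditional at "
                               "iteration %d", it + 1);
            d = std::sqrt(d);
            P(c, c) = d;
            for (int r2 = c + 1; r2 < m; ++r2) {
              double s2 = P(r2, c);
              for (int c2 = 0; c2 < c; ++c2) s2 -= P(r2, c2) * P(c, c2);
              P(r2, c) = s2 / d;
            }
          }
          // w = L^{-1} b (forward), then mean+noise via back substitution
          for (int r2 = 0; r2 < m; ++r2) {
            double s2 = b(r2);
            for (int c2 = 0; c2 < r2; ++c2) s2 -= P(r2, c2) * w(c2);
            w(r2) = s2 / P(r2, r2);
          }
          for (int r2 = 0; r2 < m; ++r2) zr(r2) = norm_rand();
          // v1_i = L'^{-1} (w + z)
          for (int r2 = m - 1; r2 >= 0; --r2) {
            double s2 = w(r2) + zr(r2);
            for (int c2 = r2 + 1; c2 < m; ++c2) s2 -= P(c2, r2) * v1(i, c2);
            v1(i, r2) = s2 / P(r2, r2);
          }
        }
      }

      // --- interweaving sweeps (ancillary-sufficient reparameterisation):
      // the likelihood identifies mu_k only jointly with the group means
      // of v0 and v1, so re-draw mu_k in the centred parameterisation,
      // where its conditional is prior-conjugate, and shift the random
      // effects accordingly. Leaves the posterior invariant, removes the
      // random-walk coupling between mu and the random-effect means.
      {
        double pp = hierarchical_mu ? 1.0 / sigma_mu_sq : mu_prior_prec;
        double pm = hierarchical_mu ? mu_mu : 0.0;
        // centred in v0: eta_i = mu_k + v0_i ~ N(mu_k, sigma0^2)
        arma::vec eta_sum(K, arma::fill::zeros);
        arma::ivec nk(K, arma::fill::zeros);
        for (int i = 0; i < N; ++i) {
          int k = group(i) - 1;
          eta_sum(k) += mu(k) + v0(i);
          nk(k) += 1;
        }
        for (int k = 0; k < K; ++k) {
          double prec = nk(k) / sigma0_sq + pp;
          double mean = (eta_sum(k) / sigma0_sq + pm * pp) / prec;
          double mu_new = mean + norm_rand() / std::sqrt(prec);
          double shift = mu_new - mu(k);
          mu(k) = mu_new;
          for (int i = 0; i < N; ++i)
            if (group(i) - 1 == k) v0(i) -= shift;
        }
        // centred in v1: u_i = v1_i + mu_k 1 ~ N(mu_k 1, Sigma)
        double oso = arma::accu(SigmaInv);  // 1' Sigma^{-1} 1
        arma::vec si_rows = arma::sum(SigmaInv, 1);
        arma::vec s1(K, arma::fill::zeros);
        for (int i = 0; i < N; ++i) {
          int k = group(i) - 1;
          for (int j = 0; j < m; ++j)
            s1(k) += si_rows(j) * (v1(i, j) + mu(k));
        }
        for (int k = 0; k < K; ++k) {
          double prec = nk(k) * oso + pp;
          double mean = (s1(k) + pm * pp) / prec;
          double mu_new = mean + norm_rand() / std::sqrt(prec);
          double shift = mu_new - mu(k);
          mu(k) = mu_new;
          for (int i = 0; i < N; ++i)
            if (group(i) - 1 == k)
              for (int j = 0; j < m; ++j) v1(i, j) -= shift;
        }
      }

      // --- sigma0^2 | v0
      sigma0_sq = rinvgamma(ig_shape + 0.5 * N,
                            ig_scale + 0.5 * arma::dot(v0, v0));

      // --- Sigma^{-1} | v1 : Wishart(I_m, m) prior
      arma::mat Sc = arma::eye(m, m) + v1.t() * v1;
      SigmaInv = rwishart(arma::inv_sympd(Sc), m + N);
    }

    if (!mu.is_finite())
      stop("sampler diverged (non-finite state) at iteration %d", it + 1);

    if (it >= n_burnin && (it - n_burnin) % thin == 0 && s_out < S) {
      mu_store.row(s_out) = mu.t();
      if (p > 0) beta_store.row(s_out) = beta.t();
      sigma0_store(s_out) = sigma0_sq;
      ++s_out;
    }
  }

  return List::create(_["mu"] = mu_store,
                      _["beta"] = (p > 0) ? wrap(beta_store)
                                          : wrap(arma::mat(0, 0)),
                      _["sigma_v0_sq"] = sigma0_store,
                      _["Sigma"] = arma::inv_sympd(SigmaInv));
}
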