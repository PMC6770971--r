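// Polya-Gamma PG(b, z) sampling.
//
// PG(1, z) uses the exact alternating-series rejection sampler of Devroye
// (2009) as specialised by Polson, Scott & Windle (2013): the target is
// J*(1, z/2)/4, proposals mix a truncated inverse-Gaussian with a shifted
// exponential at the crossover point t = 0.64.
//
// PG(b, z) for integer b is a b-fold convolution of PG(1, z); beyond
// `exact_max` trials we switch to a moment-matched normal (the summands are
// iid with mild skew, so the CLT approximation is accurate at b ~ 15+, and
// augmentation variables are nuisance quantities).

#include <Rcpp.h>
#include "polyagamma.h"

static const double PG_TRUNC = 0.64;

// Piecewise series coefficient a_n(x) for the J*(1,.) density.
static double pg_acoef(int n, double x) {
  double h = n + 0.5;
  if (x > PG_TRUNC)
    return M_PI * h * std::exp(-0.5 * h * h * M_PI * M_PI * x);
  return M_PI * h * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * h * h / x);
}

// P(X <= x) for inverse-Gaussian(mu = 1/z, lambda = 1), in a form stable
// for small z (uses log pnorm to avoid overflow in exp(2z)).
static double pg_pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double b = rx * (x * z - 1.0);
  double a = -rx * (x * z + 1.0);
  double lo = 2.0 * z + R::pnorm(a, 0.0, 1.0, 1, 1);
  return R::pnorm(b, 0.0, 1.0, 1, 0) + std::exp(lo);
}

// Probability that the proposal comes from the exponential (right) piece.
static double pg_right_mass(double z) {
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double rp = 0.5 * M_PI / fz * std::exp(-fz * PG_TRUNC);       // right piece
  double lp = 2.0 * std::exp(-z) * pg_pigauss(PG_TRUNC, z);     // left piece
  return rp / (rp + lp);
}

// Inverse-Gaussian(1/z, 1) truncated to (0, PG_TRUNC].
static double pg_rtigauss(double z) {
  double t = PG_TRUNC;
  double x = t + 1.0;
  if (z < 1.0 / t) {
    // small z: rejection from truncated chi-squared proposal
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  double mu = 1.0 / z;
  while (x > t) {
    double y = norm_rand();
    y = y * y;
    double muy = mu * y;
    x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
  }
  return x;
}

double rpg_one(double z) {
  z = 0.5 * std::fabs(z);
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double pright = pg_right_mass(z);
  for (;;) {
    double x = (unif_rand() < pright) ? PG_TRUNC + R::exp_rand() / fz
                                      : pg_rtigauss(z);
    // squeeze acceptance via the alternating series
    double s = pg_acoef(0, x);
    double y = unif_rand() * s;
    for (int n = 1;; ++n) {
      if (n % 2 == 1) {
        s -= pg_acoef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += pg_acoef(n, x);
        if (y > s) break;
      }
    }
  }
}

// mean and variance of PG(1, z); z may be 0
static void pg_moments(double z, double *mean, double *var) {
  z = std::fabs(z);
  if (z < 1e-6) {
    // series limits: E = 1/4 - z^2/24..., V = 1/24 - ...
    *mean = 0.25 - z * z / 24.0;
    *var = 1.0 / 24.0;
    return;
  }
  double th = std::tanh(0.5 * z);
  *mean = 0.5 * th / z;
  double sech2 = 1.0 - th * th;  // sech^2(z/2)
  // sinh(z) sech^2(z/2) = 2 tanh(z/2): overflow-free form of
  // (sinh(z) - z) sech^2(z/2) / (4 z^3)
  *var = (2.0 * th - z * sech2) / (4.0 * z * z * z);
}

double rpg(int b, double z, int exact_max) {
  if (b <= 0) return 0.0;
  if (b <= exact_max) {
    double s = 0.0;
    for (int i = 0; i < b; ++i) s += rpg_one(z);
    return s;
  }
  double m1, v1;
  pg_moments(z, &m1, &v1);
  double mean = b * m1, sd = std::sqrt(b * v1);
  double x;
  do {
    x = mean + sd * norm_rand();
  } while (x <= 0.0);
  return x;
}

// [[Rcpp::export(name = ".rpg_vec")]]
Rcpp::NumericVector rpg_vec(Rcpp::IntegerVector b, Rcpp::NumericVector z,
                            int exact_max = 40) {
  int n = b.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg(b[i], z[i], exact_max);
  return out;
}
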