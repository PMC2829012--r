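#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Gibbs samplers for the three hierarchical tag-count models.  Full
// conditionals are conjugate throughout, so every sweep is a sequence of
// vectorised Poisson / gamma draws.  Thinned post-burn-in proportion vectors
// are returned as a kept-by-genes matrix.

static inline int n_kept_of(int n_iter, int burn_in, int thin) {
  return (n_iter - burn_in) / thin;
}

// Dirichlet-Poisson-Binomial: t_i ~ Bin(g_i, phi_i), g_i ~ Pois(N m_i),
// m ~ Dir(alpha), N ~ ceiling(Gamma(shape gamma1, scale gamma2)).
// Conditionals: g_i <- t_i + Pois(N m_i (1 - phi_i)); m <- Dir(alpha + g);
// N <- ceiling(Gamma(gamma1 + sum g, rate 1/gamma2 + 1)).
// [[Rcpp::export]]
List dpb_gibbs_cpp(IntegerVector t, NumericVector phi, NumericVector alpha,
                   double gamma_shape, double gamma_scale,
                   int n_iter, int burn_in, int thin, int seed,
                   NumericVector m_init, double n_init, bool keep_g) {
  const int l = t.size();
  const int n_kept = n_kept_of(n_iter, burn_in, thin);
  TagRng rng((uint64_t)seed);

  NumericMatrix m_out(n_kept, l);
  NumericVector n_out(n_kept);
  IntegerMatrix g_out = keep_g ? IntegerMatrix(n_kept, l) : IntegerMatrix(0, 0);

  std::vector<double> m(m_init.begin(), m_init.end());
  std::vector<double> g(l), shape(l);
  double N = n_init;
  const double rate = 1.0 / gamma_scale + 1.0;
  int clamps = 0, kept = 0;

  for (int it = 1; it <= n_iter; it++) {
    double sum_g = 0.0;
    for (int i = 0; i < l; i++) {
      g[i] = t[i] + rng.pois(N * m[i] * (1.0 - phi[i]));
      sum_g += g[i];
      shape[i] = alpha[i] + g[i];
    }
    clamps += rng.dirichlet(shape.data(), m.data(), l);
    N = std::ceil(rng.gamma_ge1(gamma_shape + sum_g) / rate);
    if (!std::isfinite(N))
      stop("DPB population-size update overflowed (non-finite N)");
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int i = 0; i < l; i++) m_out(kept, i) = m[i];
      if (keep_g)
        for (int i = 0; i < l; i++) g_out(kept, i) = (int)g[i];
      n_out[kept] = N;
      kept++;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["m"] = m_out, _["N"] = n_out,
                          _["clamps"] = clamps);
  if (keep_g) out["g"] = g_out;
  return out;
}

// Dirichlet-Multinomial-Binomial: N ~ Pois(lambda), g | N ~ Mult(N, m),
// t_i | g_i ~ Bin(g_i, phi_i), m ~ Dir(alpha).  Conditionals:
// u_i <- Pois(lambda m_i (1 - phi_i)); g = t + u; m <- Dir(alpha + g);
// optionally lambda <- Gamma(gamma1 + sum g, rate 1/gamma2 + 1).
// [[Rcpp::export]]
List dmb_gibbs_cpp(IntegerVector t, NumericVector phi, NumericVector alpha,
                   double lambda_init, bool update_lambda,
                   double gamma_shape, double gamma_scale,
                   int n_iter, int burn_in, int thin, int seed,
                   NumericVector m_init, bool keep_u) {
  const int l = t.size();
  const int n_kept = n_kept_of(n_iter, burn_in, thin);
  TagRng rng((uint64_t)seed);

  NumericMatrix m_out(n_kept, l);
  NumericVector lambda_out(n_kept), utot_out(n_kept);
  IntegerMatrix u_out = keep_u ? IntegerMatrix(n_kept, l) : IntegerMatrix(0, 0);

  std::vector<double> m(m_init.begin(), m_init.end());
  std::vector<int> u(l);
  std::vector<double> shape(l);
  double lambda = lambda_init;
  const double rate = 1.0 / gamma_scale + 1.0;
  int clamps = 0, kept = 0;

  for (int it = 1; it <= n_iter; it++) {
    double sum_g = 0.0, sum_u = 0.0;
    for (int i = 0; i < l; i++) {
      u[i] = rng.pois(lambda * m[i] * (1.0 - phi[i]));
      sum_u += u[i];
      double gi = t[i] + u[i];
      sum_g += gi;
      shape[i] = alpha[i] + gi;
    }
    clamps += rng.dirichlet(shape.data(), m.data(), l);
    if (update_lambda) {
      lambda = rng.gamma_ge1(gamma_shape + sum_g) / rate;
      if (!std::isfinite(lambda))
        stop("DMB population-size update overflowed (non-finite lambda)");
    }
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int i = 0; i < l; i++) m_out(kept, i) = m[i];
      if (keep_u)
        for (int i = 0; i < l; i++) u_out(kept, i) = u[i];
      lambda_out[kept] = lambda;
      utot_out[kept] = sum_u;
      kept++;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["m"] = m_out, _["lambda"] = lambda_out,
                          _["u_total"] = utot_out, _["clamps"] = clamps);
  if (keep_u) out["u"] = u_out;
  return out;
}

// Missing-data model: augmented vector q over l + 1 categories,
// q | r ~ Dir(t + alpha, r + 1); r | q0 ~ Pois(mu q0).
// [[Rcpp::export]]
List md_gibbs_cpp(IntegerVector t, NumericVector alpha, double mu,
                  int n_iter, int burn_in, int thin, int seed, double r_init) {
  const int l = t.size();
  const int n_kept = n_kept_of(n_iter, burn_in, thin);
  TagRng rng((uint64_t)seed);

  NumericMatrix q_out(n_kept, l + 1);
  NumericVector r_out(n_kept);

  std::vector<double> q(l + 1), shape(l + 1);
  double r = r_init;
  for (int i = 0; i < l; i++) shape[i] = t[i] + alpha[i];
  int clamps = 0, kept = 0;

  for (int it = 1; it <= n_iter; it++) {
    shape[l] = r + 1.0;
    clamps += rng.dirichlet(shape.data(), q.data(), l + 1);
    r = rng.pois(mu * q[l]);
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int i = 0; i <= l; i++) q_out(kept, i) = q[i];
      r_out[kept] = r;
      kept++;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["q"] = q_out, _["r"] = r_out, _["clamps"] = clamps);
}

// Test hooks for the internal generators (see test-rng.R).
// [[Rcpp::export]]
NumericVector rng_draws_cpp(int n, int seed, std::string kind, double par) {
  TagRng rng((uint64_t)seed);
  NumericVector out(n);
  if (kind == "unif") {
    for (int i = 0; i < n; i++) out[i] = rng.unif();
  } else if (kind == "norm") {
    for (int i = 0; i < n; i++) out[i] = rng.normal();
  } else if (kind == "gamma") {
    for (int i = 0; i < n; i++) out[i] = rng.gamma(par);
  } else if (kind == "gamma_log") {
    if (par >= 1.0) stop("gamma_log is for shape < 1");
    for (int i = 0; i < n; i++) out[i] = rng.log_gamma_lt1(par);
  } else if (kind == "pois") {
    for (int i = 0; i < n; i++) out[i] = (double)rng.pois(par);
  } else {
    stop("unknown kind");
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix rdirichlet_cpp(int n, NumericVector shape, int seed) {
  const int l = shape.size();
  TagRng rng((uint64_t)seed);
  NumericMatrix out(n, l);
  std::vector<double> m(l);
  for (int i = 0; i < n; i++) {
    rng.dirichlet(REAL(shape), m.data(), l);
    for (int j = 0; j < l; j++) out(i, j) = m[j];
  }
  return out;
}
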