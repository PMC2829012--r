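#ifndef TAGBAYES_RNG_H
#define TAGBAYES_RNG_H

#include <cstdint>
#include <cmath>
#include <cstdlib>

// Self-contained RNG stack for the Gibbs inner loops: xoshiro256++ uniforms,
// ziggurat normals, Marsaglia-Tsang gammas (log-space boost below shape 1),
// Poisson by inversion for small means and Hormann's PTRS rejection above.
// The samplers draw ~1e10 variates in a full coverage study, which rules out
// going through R's generator call-by-call.

class TagRng {
  uint64_t s[4];
  uint32_t kn[128];
  double wn[128], fn[128];

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  void zig_setup() {
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    const double m1 = 2147483648.0;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  int pois_ptrs(double mu) {
    // Hormann (1993) transformed rejection with squeeze; valid for mu >= 10.
    double smu = std::sqrt(mu);
    double b = 0.931 + 2.53 * smu;
    double a = -0.059 + 0.02483 * b;
    double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
    double v_r = 0.9277 - 3.6224 / (b - 2.0);
    double lmu = std::log(mu);
    for (;;) {
      double U = unif() - 0.5;
      double V = unif();
      double us = 0.5 - std::fabs(U);
      double kd = std::floor((2.0 * a / us + b) * U + mu + 0.43);
      if (us >= 0.07 && V <= v_r) return (int)kd;
      if (kd < 0.0 || (us < 0.013 && V > us)) continue;
      if (std::log(V) + std::log(inv_alpha) - std::log(a / (us * us) + b) <=
          kd * lmu - mu - std::lgamma(kd + 1.0))
        return (int)kd;
    }
  }

 public:
  explicit TagRng(uint64_t seed) {
    // splitmix64 expansion of the seed into the xoshiro state
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    zig_setup();
  }

  inline uint64_t next_u64() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // strictly inside (0, 1)
  inline double unif() {
    return ((double)(next_u64() >> 12) + 0.5) * (1.0 / 4503599627370496.0);
  }

  double normal() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)next_u64();
      uint32_t iz = (uint32_t)(hz & 127);
      uint32_t ahz = (uint32_t)((hz < 0) ? -(int64_t)hz : (int64_t)hz);
      if (ahz < kn[iz]) return hz * wn[iz];
      const double r = 3.442619855899;
      if (iz == 0) {
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }

  // Marsaglia-Tsang; requires shape >= 1
  double gamma_ge1(double a) {
    double d = a - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do {
        x = normal();
        v = 1.0 + c * x;
      } while (v <= 0.0);
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }

  // log of a Gamma(a, 1) draw for a < 1 (boosted, never underflows in log space)
  double log_gamma_lt1(double a) {
    return std::log(gamma_ge1(a + 1.0)) + std::log(unif()) / a;
  }

  double gamma(double a) {
    if (a >= 1.0) return gamma_ge1(a);
    return std::exp(log_gamma_lt1(a));  // may underflow for tiny a
  }

  int pois(double mu) {
    if (mu <= 0.0) return 0;
    if (mu < 10.0) {
      double u = unif();
      double p = std::exp(-mu), F = p;
      int k = 0;
      while (u > F && k < 1000) {
        k++;
        p *= mu / k;
        F += p;
      }
      return k;
    }
    return pois_ptrs(mu);
  }

  // Dirichlet draw into m; shapes < 1 go through the log-space boost and a
  // residual underflow is clamped to 1e-300; returns the number of clamps.
  int dirichlet(const double* shape, double* m, int l) {
    int clamps = 0;
    double sum = 0.0;
    for (int i = 0; i < l; i++) {
      double x;
      if (shape[i] >= 1.0) {
        x = gamma_ge1(shape[i]);
      } else {
        x = std::exp(log_gamma_lt1(shape[i]));
      }
      if (x < 1e-300 || !std::isfinite(x)) {  // incl. subnormals that would
        x = 1e-300;                           // underflow after normalising
        clamps++;
      }
      m[i] = x;
      sum += x;
    }
    for (int i = 0; i < l; i++) m[i] /= sum;
    return clamps;
  }
};

#endif
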