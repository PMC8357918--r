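// Deterministic Gaussian stream for sensor-noise synthesis.
//
// xoshiro256++ seeded via splitmix64, Box-Muller transform: platform-stable
// (integer state, IEEE doubles), independent of R's global RNG, and fast
// enough for tens of millions of draws per session.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

static inline uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return (double(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// [[Rcpp::export]]
Rcpp::NumericVector gaussian_stream_cpp(double n, double seed) {
  const R_xlen_t N = static_cast<R_xlen_t>(n);
  Rcpp::NumericVector out(N);
  Xoshiro256pp rng(static_cast<uint64_t>(seed));
  const double twopi = 6.283185307179586476925286766559;
  R_xlen_t i = 0;
  while (i < N) {
    const double u1 = rng.unif(), u2 = rng.unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    out[i++] = r * std::cos(twopi * u2);
    if (i < N) out[i++] = r * std::sin(twopi * u2);
  }
  return out;
}
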