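#ifndef DEMOSEL_RNG_H
#define DEMOSEL_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained xoshiro256++ generator. Streams are fully determined by the
// 64-bit seed, independent of compiler library implementations, so simulation
// output is reproducible bit-for-bit across builds.
class XRng {
public:
  explicit XRng(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    haveNorm = false;
  }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0,1)
  double unif() {
    return (((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0));
  }

  double rexp() { return -std::log(unif()); }

  double rnorm() {
    if (haveNorm) { haveNorm = false; return cachedNorm; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cachedNorm = r * std::sin(2.0 * M_PI * u2);
    haveNorm = true;
    return r * std::cos(2.0 * M_PI * u2);
  }

  // Poisson; Knuth for small means, normal approximation for large ones
  // (means here are branch-level mutation counts, crossover counts, etc.)
  int rpois(double mean) {
    if (mean <= 0.0) return 0;
    if (mean < 50.0) {
      double L = std::exp(-mean), p = 1.0;
      int k = 0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    double v = mean + std::sqrt(mean) * rnorm();
    if (v < 0.0) v = 0.0;
    return (int)(v + 0.5);
  }

  // integer in [0, n)
  int runifInt(int n) {
    return (int)(unif() * n) % n;
  }

private:
  static uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t s[4];
  bool haveNorm;
  double cachedNorm;
};

#endif
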