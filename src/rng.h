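#pragma once
#include <cstdint>
#include <cmath>

// xoroshiro128+ with splitmix64 seeding; one sub-stream per decay so results
// are independent of batching order.
struct RNG {
  uint64_t s0, s1;
  bool have_cache = false;
  double cache = 0.0;

  static inline uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t base, uint64_t stream) {
    uint64_t x = base ^ (stream * 0xD6E8FEB86659FD93ULL + 0xA5A5A5A5A5A5A5A5ULL);
    s0 = splitmix(x);
    s1 = splitmix(x);
    if (!(s0 | s1)) s0 = 0x9E3779B97F4A7C15ULL;
    have_cache = false;
  }

  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = rotl(a, 55) ^ b ^ (b << 14);
    s1 = rotl(b, 36);
    return r;
  }

  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  inline double unifpos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  inline double expdev() { return -std::log(unifpos()); }

  double normal() {
    if (have_cache) { have_cache = false; return cache; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cache = v * f;
    have_cache = true;
    return u * f;
  }

  // Poisson: Knuth for small mean, normal approximation for large
  long poisson(double mean) {
    if (mean <= 0) return 0;
    if (mean < 500.0) {
      double L = std::exp(-mean), p = 1.0;
      long k = 0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    double n = mean + std::sqrt(mean) * normal();
    if (n < 0) n = 0;
    return (long)(n + 0.5);
  }
};
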