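#pragma once

#include <cstdint>
#include <cmath>

// Self-contained PRNG so that per-condition streams are reproducible
// bit-for-bit across platforms and independent of R's global RNG state.

struct SplitMix64 {
  uint64_t x;
  explicit SplitMix64(uint64_t seed) : x(seed) {}
  uint64_t next() {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    SplitMix64 sm(seed);
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform on (0, 1): safe operand for log()
  inline double unif_open() { return ((next() >> 12) + 0.5) * 0x1.0p-52; }
};

// Stream seed for condition k derived from a base seed; used for both the
// knockout screen and one-at-a-time simulation so the two agree exactly.
inline uint64_t grn_stream_seed(uint64_t base, uint64_t k) {
  SplitMix64 sm(base ^ (0xA0761D6478BD642FULL * (k + 1)));
  return sm.next();
}

// Marsaglia-Tsang ziggurat for standard normals (128 layers).
class ZigguratNormal {
  uint32_t kn_[128];
  double wn_[128], fn_[128];

 public:
  ZigguratNormal() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;

    double q = vn / std::exp(-0.5 * dn * dn);
    kn_[0] = static_cast<uint32_t>((dn / q) * m1);
    kn_[1] = 0;
    wn_[0] = q / m1;
    wn_[127] = dn / m1;
    fn_[0] = 1.0;
    fn_[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn_[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn_[i] = std::exp(-0.5 * dn * dn);
      wn_[i] = dn / m1;
    }
  }

  inline double draw(Xoshiro256pp& rng) {
    const double r = 3.442620;  // start of the right tail
    for (;;) {
      const int32_t hz = static_cast<int32_t>(static_cast<uint32_t>(rng.next()));
      const uint32_t iz = static_cast<uint32_t>(hz) & 127u;
      const int64_t ahz = hz >= 0 ? static_cast<int64_t>(hz) : -static_cast<int64_t>(hz);
      if (ahz < static_cast<int64_t>(kn_[iz])) return hz * wn_[iz];

      if (iz == 0) {  // tail via Marsaglia's method
        double x, y;
        do {
          x = -std::log(rng.unif_open()) / r;
          y = -std::log(rng.unif_open());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      const double x = hz * wn_[iz];
      if (fn_[iz] + rng.unif() * (fn_[iz - 1] - fn_[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};
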