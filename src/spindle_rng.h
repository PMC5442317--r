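#ifndef SPINDLE_RNG_H
#define SPINDLE_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256** with splitmix64 seeding. Self-contained counter-free stream so
// simulation runs are bitwise reproducible from an integer seed and do not
// touch R's global RNG state.
class Rng {
 public:
  explicit Rng(uint64_t seed) { reseed(seed); }
  void reseed(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s_[i] = t ^ (t >> 31);
    }
    have_cached_ = false;
  }

  uint64_t next_u64() {
    const uint64_t result = rotl(s_[1] * 5, 7) * 9;
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }

  // uniform on (0,1)
  double runif() {
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal via the Marsaglia-Tsang ziggurat (128 layers) with the
  // exact exponential-rejection tail
  double rnorm() {
    const Zig& z = zig();
    for (;;) {
      int64_t hz = (int32_t)(uint32_t)(next_u64() >> 32);
      int iz = (int)(hz & 127);
      if (hz > -z.kn[iz] && hz < z.kn[iz]) return hz * z.wn[iz];
      double x = hz * z.wn[iz];
      if (iz == 0) {
        double xx, yy;
        do {
          xx = -std::log(runif()) / z.r;
          yy = -std::log(runif());
        } while (yy + yy < xx * xx);
        return hz > 0 ? z.r + xx : -(z.r + xx);
      }
      if (z.fn[iz] + runif() * (z.fn[iz - 1] - z.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }

 private:
  struct Zig {
    int64_t kn[128];
    double wn[128], fn[128];
    double r;
  };
  static const Zig& zig() {
    static const Zig z = make_zig();
    return z;
  }
  static Zig make_zig() {
    Zig z;
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    z.r = dn;
    double q = vn / std::exp(-0.5 * dn * dn);
    z.kn[0] = (int64_t)((dn / q) * m1);
    z.kn[1] = 0;
    z.wn[0] = q / m1;
    z.wn[127] = dn / m1;
    z.fn[0] = 1.0;
    z.fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      z.kn[i + 1] = (int64_t)((dn / tn) * m1);
      tn = dn;
      z.fn[i] = std::exp(-0.5 * dn * dn);
      z.wn[i] = dn / m1;
    }
    return z;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t s_[4];
  bool have_cached_ = false;
};

#endif
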