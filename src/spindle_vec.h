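#ifndef SPINDLE_VEC_H
#define SPINDLE_VEC_H

#include <cmath>

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3 operator-() const { return Vec3(-x, -y, -z); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
};

inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm2(const Vec3& a) { return dot(a, a); }
inline double norm(const Vec3& a) { return std::sqrt(norm2(a)); }
inline Vec3 normalize(const Vec3& a) {
  double n = norm(a);
  return (n > 0) ? a * (1.0 / n) : Vec3(1, 0, 0);
}

// orthonormal pair perpendicular to unit vector n
inline void perp_basis(const Vec3& n, Vec3& p1, Vec3& p2) {
  if (std::fabs(n.x) < 0.9)
    p1 = normalize(cross(n, Vec3(1, 0, 0)));
  else
    p1 = normalize(cross(n, Vec3(0, 1, 0)));
  p2 = cross(n, p1);
}

// closest points between segments A (a0 + s*da, s in [0,1]) and B (b0 + t*db)
// returns squared distance; sets s and t.
inline double segment_segment_dist2(const Vec3& a0, const Vec3& da,
                                    const Vec3& b0, const Vec3& db,
                                    double& s, double& t) {
  const Vec3 r = a0 - b0;
  const double a = dot(da, da), e = dot(db, db), f = dot(db, r);
  const double c = dot(da, r), b = dot(da, db);
  const double denom = a * e - b * b;
  if (denom > 1e-14 * a * e + 1e-300)
    s = (b * f - c * e) / denom;
  else
    s = 0.0;  // near-parallel: pick an end, clamp below
  if (s < 0) s = 0; else if (s > 1) s = 1;
  t = (e > 0) ? (b * s + f) / e : 0.0;
  if (t < 0) {
    t = 0;
    s = (a > 0) ? -c / a : 0.0;
    if (s < 0) s = 0; else if (s > 1) s = 1;
  } else if (t > 1) {
    t = 1;
    s = (a > 0) ? (b - c) / a : 0.0;
    if (s < 0) s = 0; else if (s > 1) s = 1;
  }
  const Vec3 d = (a0 + da * s) - (b0 + db * t);
  return norm2(d);
}

#endif
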