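#ifndef CCCMR_CORE_H
#define CCCMR_CORE_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

namespace cccmr {

constexpr double ME = 0.51099895;       // electron rest energy, MeV
constexpr double RE = 2.8179403262e-13; // classical electron radius, cm
constexpr double EPG = 3.342796e23;     // electrons per gram of water (Z/A = 0.55509)
constexpr double X0_WATER = 36.08;      // radiation length of water, g/cm2
constexpr double TWO_ME = 2.0 * ME;     // pair production threshold, MeV

// ---------------------------------------------------------------------------
// Counter-based RNG: per-history streams from splitmix64 -> xoshiro256**.
// A history is fully determined by (seed, stream), independent of scheduling.
// ---------------------------------------------------------------------------
struct RNG {
  uint64_t s[4];
  bool has_gauss = false;
  double gauss_cache = 0.0;

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  RNG(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0x9E3779B97F4A7C15ULL + 0x632BE59BD9B4E019ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; } // [0, 1)
  double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  double gauss() {
    if (has_gauss) { has_gauss = false; return gauss_cache; }
    double u1, u2, r2;
    do {
      u1 = 2.0 * unif() - 1.0;
      u2 = 2.0 * unif() - 1.0;
      r2 = u1 * u1 + u2 * u2;
    } while (r2 >= 1.0 || r2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(r2) / r2);
    gauss_cache = u2 * f;
    has_gauss = true;
    return u1 * f;
  }
};

// ---------------------------------------------------------------------------
// Table lookup: log-log interpolation of the source table resampled onto a
// fine uniform-energy lattice, so value() is a transcendental-free linear
// interpolation.
// ---------------------------------------------------------------------------
struct FastTable {
  double E0 = 0.0, dE = 1.0;
  int n = 0;
  std::vector<double> V;

  void init(const Rcpp::NumericVector& E, const Rcpp::NumericVector& Vt,
            int m = 8192) {
    n = m;
    E0 = E[0];
    dE = (E[E.size() - 1] - E0) / (n - 1);
    V.resize(n);
    std::vector<double> le(E.size()), lv(E.size());
    for (int i = 0; i < (int)E.size(); ++i) {
      le[i] = std::log(E[i]);
      lv[i] = std::log(Vt[i]);
    }
    for (int i = 0; i < n; ++i) {
      const double x = std::log(E0 + i * dE);
      auto it = std::upper_bound(le.begin(), le.end(), x);
      int j = (int)(it - le.begin()) - 1;
      if (j < 0) j = 0;
      if (j > (int)le.size() - 2) j = (int)le.size() - 2;
      const double w = (x - le[j]) / (le[j + 1] - le[j]);
      V[i] = std::exp(lv[j] + w * (lv[j + 1] - lv[j]));
    }
  }
  double value(double E) const {
    double t = (E - E0) / dE;
    if (t < 0.0) t = 0.0;
    if (t > n - 1.000001) t = n - 1.000001;
    const int j = (int)t;
    const double w = t - j;
    return V[j] + w * (V[j + 1] - V[j]);
  }
};

// Klein-Nishina total cross section per electron (cm^2), k = E/me.
inline double kn_sigma(double k) {
  const double t = 1.0 + 2.0 * k;
  const double s = (1.0 + k) / (k * k) * (2.0 * (1.0 + k) / t - std::log(t) / k) +
                   std::log(t) / (2.0 * k) - (1.0 + 3.0 * k) / (t * t);
  return 2.0 * M_PI * RE * RE * s;
}
inline double mu_kn_over_rho(double E) { return kn_sigma(E / ME) * EPG; }

// Sample a Compton event (Klein-Nishina on free electrons at rest).
// On return: eps = E'/E, cost = photon polar scattering cosine.
inline void sample_kn(double E, RNG& rng, double& eps, double& cost) {
  const double k = E / ME;
  const double eps0 = 1.0 / (1.0 + 2.0 * k);
  const double a1 = -std::log(eps0);
  const double a2 = 0.5 * (1.0 - eps0 * eps0);
  double sint2, g;
  for (;;) {
    if (rng.unif() * (a1 + a2) < a1) {
      eps = std::exp(-a1 * rng.unif());
    } else {
      eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * rng.unif());
    }
    const double t = (1.0 - eps) / (k * eps);
    sint2 = t * (2.0 - t);
    g = 1.0 - eps * sint2 / (1.0 + eps * eps);
    if (rng.unif() <= g) break;
  }
  cost = 1.0 - (1.0 - eps) / (k * eps);
}

// Rotate local-frame vector v (defined wrt +z) into the frame whose z-axis is w.
inline void rotate_to_frame(const double w[3], const double v[3], double out[3]) {
  const double wz = w[2];
  if (wz > 0.999999999) { out[0] = v[0]; out[1] = v[1]; out[2] = v[2]; return; }
  if (wz < -0.999999999) { out[0] = v[0]; out[1] = -v[1]; out[2] = -v[2]; return; }
  // orthonormal basis (u1, u2, w)
  const double st = std::sqrt(w[0] * w[0] + w[1] * w[1]);
  const double u1[3] = { w[0] * wz / st, w[1] * wz / st, -st };
  const double u2[3] = { -w[1] / st, w[0] / st, 0.0 };
  for (int i = 0; i < 3; ++i)
    out[i] = v[0] * u1[i] + v[1] * u2[i] + v[2] * w[i];
}

// Rodrigues rotation of v about unit axis a by angle phi (in place).
inline void rotate_about(double v[3], const double a[3], double phi) {
  const double c = std::cos(phi), s = std::sin(phi);
  const double d = a[0] * v[0] + a[1] * v[1] + a[2] * v[2];
  const double cr[3] = { a[1] * v[2] - a[2] * v[1],
                         a[2] * v[0] - a[0] * v[2],
                         a[0] * v[1] - a[1] * v[0] };
  for (int i = 0; i < 3; ++i)
    v[i] = v[i] * c + cr[i] * s + a[i] * d * (1.0 - c);
}

inline void renormalize(double v[3]) {
  const double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= n; v[1] /= n; v[2] /= n;
}

// Rodrigues rotation with precomputed cos/sin (axis fixed during transport).
inline void rotate_about_cached(double v[3], const double a[3], double c,
                                double s) {
  const double d = a[0] * v[0] + a[1] * v[1] + a[2] * v[2];
  const double cr[3] = { a[1] * v[2] - a[2] * v[1],
                         a[2] * v[0] - a[0] * v[2],
                         a[0] * v[1] - a[1] * v[0] };
  for (int i = 0; i < 3; ++i)
    v[i] = v[i] * c + cr[i] * s + a[i] * d * (1.0 - c);
}

// Small-angle multiple-scattering deflection: add two transverse Gaussian
// angle components in an orthonormal frame around dir and renormalize.
inline void deflect_small_angle(double dir[3], double tx, double ty) {
  double e1[3];
  if (std::fabs(dir[2]) < 0.9) { e1[0] = -dir[1]; e1[1] = dir[0]; e1[2] = 0.0; }
  else { e1[0] = 0.0; e1[1] = -dir[2]; e1[2] = dir[1]; }
  renormalize(e1);
  const double e2[3] = { dir[1] * e1[2] - dir[2] * e1[1],
                         dir[2] * e1[0] - dir[0] * e1[2],
                         dir[0] * e1[1] - dir[1] * e1[0] };
  dir[0] += tx * e1[0] + ty * e2[0];
  dir[1] += tx * e1[1] + ty * e2[1];
  dir[2] += tx * e1[2] + ty * e2[2];
  renormalize(dir);
}

// ---------------------------------------------------------------------------
// Cartesian voxel grid
// ---------------------------------------------------------------------------
struct Grid {
  int nx, ny, nz;
  double sx, sy, sz;   // spacing, cm
  double ox, oy, oz;   // corner of voxel (0,0,0)
  const double* rho;

  inline bool inside(const double p[3]) const {
    return p[0] >= ox && p[0] < ox + nx * sx &&
           p[1] >= oy && p[1] < oy + ny * sy &&
           p[2] >= oz && p[2] < oz + nz * sz;
  }
  inline int clampi(int i, int n) const { return i < 0 ? 0 : (i >= n ? n - 1 : i); }
  inline int voxel(const double p[3]) const {
    const int i = clampi((int)std::floor((p[0] - ox) / sx), nx);
    const int j = clampi((int)std::floor((p[1] - oy) / sy), ny);
    const int k = clampi((int)std::floor((p[2] - oz) / sz), nz);
    return i + nx * (j + ny * k);
  }
  inline double density(const double p[3]) const {
    return inside(p) ? rho[voxel(p)] : 0.0;
  }
};

// Clip ray p0 + t*dir to the grid box; returns false if it misses.
inline bool clip_to_box(const Grid& g, const double p0[3], const double dir[3],
                        double tmax, double& t_in, double& t_out) {
  t_in = 0.0; t_out = tmax;
  const double lo[3] = { g.ox, g.oy, g.oz };
  const double hi[3] = { g.ox + g.nx * g.sx, g.oy + g.ny * g.sy, g.oz + g.nz * g.sz };
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-14) {
      if (p0[a] < lo[a] || p0[a] >= hi[a]) return false;
    } else {
      double t1 = (lo[a] - p0[a]) / dir[a];
      double t2 = (hi[a] - p0[a]) / dir[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > t_in) t_in = t1;
      if (t2 < t_out) t_out = t2;
    }
  }
  return t_in < t_out;
}

// Exact voxel traversal (Siddon/Amanatides-Woo). Calls f(vox, t_in, t_out) for
// every voxel crossed by p0 + t*dir, 0 <= t <= tmax; f returns false to stop
// early. Half-open voxel convention [lower, upper).
template <class F>
inline void traverse(const Grid& g, const double p0[3], const double dir[3],
                     double tmax, F&& f) {
  double t0, t1;
  if (!clip_to_box(g, p0, dir, tmax, t0, t1)) return;
  const double eps = 1e-12 * (1.0 + std::fabs(t1));
  double pstart[3] = { p0[0] + (t0 + eps) * dir[0],
                       p0[1] + (t0 + eps) * dir[1],
                       p0[2] + (t0 + eps) * dir[2] };
  int i = g.clampi((int)std::floor((pstart[0] - g.ox) / g.sx), g.nx);
  int j = g.clampi((int)std::floor((pstart[1] - g.oy) / g.sy), g.ny);
  int k = g.clampi((int)std::floor((pstart[2] - g.oz) / g.sz), g.nz);
  const int stepi = dir[0] > 0 ? 1 : -1;
  const int stepj = dir[1] > 0 ? 1 : -1;
  const int stepk = dir[2] > 0 ? 1 : -1;
  const double INF = std::numeric_limits<double>::infinity();
  double tdx = std::fabs(dir[0]) > 1e-14 ? g.sx / std::fabs(dir[0]) : INF;
  double tdy = std::fabs(dir[1]) > 1e-14 ? g.sy / std::fabs(dir[1]) : INF;
  double tdz = std::fabs(dir[2]) > 1e-14 ? g.sz / std::fabs(dir[2]) : INF;
  auto next_cross = [&](double p, double o, double s, double d, int idx, int stp) {
    if (std::fabs(d) < 1e-14) return INF;
    const double edge = o + (idx + (stp > 0 ? 1 : 0)) * s;
    return (edge - p) / d;
  };
  double tmx = t0 + next_cross(pstart[0], g.ox, g.sx, dir[0], i, stepi);
  double tmy = t0 + next_cross(pstart[1], g.oy, g.sy, dir[1], j, stepj);
  double tmz = t0 + next_cross(pstart[2], g.oz, g.sz, dir[2], k, stepk);
  double tcur = t0;
  while (tcur < t1 - 1e-13) {
    const double tnext = std::min(std::min(tmx, tmy), std::min(tmz, t1));
    if (tnext > tcur)
      if (!f(i + g.nx * (j + g.ny * k), tcur, tnext)) return;
    if (tnext >= t1 - 1e-13) break;
    if (tmx <= tmy && tmx <= tmz) { i += stepi; tmx += tdx; if (i < 0 || i >= g.nx) break; }
    else if (tmy <= tmz)          { j += stepj; tmy += tdy; if (j < 0 || j >= g.ny) break; }
    else                          { k += stepk; tmz += tdz; if (k < 0 || k >= g.nz) break; }
    tcur = tnext;
  }
}

} // namespace cccmr

#endif
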