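// 3D gamma index (dose difference / distance to agreement), global
// normalization, native-resolution search with optional trilinear subdivision
// of the evaluated distribution.
#include "core.h"
using namespace Rcpp;
using namespace cccmr;

namespace {
struct Offset {
  double dx, dy, dz, dist2;
  int di, dj, dk; // integer part when subdivide == 1
};
}

// [[Rcpp::export]]
NumericVector cpp_gamma3d(NumericVector ref, NumericVector eval, IntegerVector dims,
                          NumericVector spacing, double dose_crit, double dta_cm,
                          double search_mult, double cutoff, int subdivide) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const double* R = REAL(ref);
  const double* E = REAL(eval);
  NumericVector gamma(nvox, NA_REAL);
  const double radius = search_mult * dta_cm;
  const double r2max = radius * radius;
  const double dd2 = dose_crit * dose_crit;
  const double dta2 = dta_cm * dta_cm;

  // candidate displacement list, sorted by distance so the DTA term allows
  // early termination
  std::vector<Offset> offs;
  const int mx = (int)std::floor(radius / (sx / subdivide));
  const int my = (int)std::floor(radius / (sy / subdivide));
  const int mz = (int)std::floor(radius / (sz / subdivide));
  for (int a = -mx; a <= mx; ++a)
    for (int b = -my; b <= my; ++b)
      for (int c = -mz; c <= mz; ++c) {
        const double dx = a * sx / subdivide, dy = b * sy / subdivide,
                     dz = c * sz / subdivide;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > r2max + 1e-12) continue;
        Offset o;
        o.dx = dx; o.dy = dy; o.dz = dz; o.dist2 = d2;
        o.di = a; o.dj = b; o.dk = c;
        offs.push_back(o);
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.dist2 < b.dist2; });

  auto eval_at = [&](int i, int j, int k) { return E[i + nx * (j + (size_t)ny * k)]; };
  // trilinear sample of eval at fractional voxel coordinates
  auto eval_frac = [&](double fi, double fj, double fk, bool& ok) {
    if (fi < 0 || fj < 0 || fk < 0 || fi > nx - 1 || fj > ny - 1 || fk > nz - 1) {
      ok = false;
      return 0.0;
    }
    ok = true;
    const int i0 = std::min((int)fi, nx - 2 < 0 ? 0 : nx - 2);
    const int j0 = std::min((int)fj, ny - 2 < 0 ? 0 : ny - 2);
    const int k0 = std::min((int)fk, nz - 2 < 0 ? 0 : nz - 2);
    const double u = fi - i0, v = fj - j0, w = fk - k0;
    double acc = 0.0;
    for (int a = 0; a <= 1; ++a)
      for (int b = 0; b <= 1; ++b)
        for (int c = 0; c <= 1; ++c) {
          const double wt = (a ? u : 1 - u) * (b ? v : 1 - v) * (c ? w : 1 - w);
          if (wt > 0) acc += wt * eval_at(std::min(i0 + a, nx - 1),
                                          std::min(j0 + b, ny - 1),
                                          std::min(k0 + c, nz - 1));
        }
    return acc;
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t v = i + nx * (j + (size_t)ny * k);
        if (R[v] < cutoff) continue;
        double best = std::numeric_limits<double>::infinity();
        for (const Offset& o : offs) {
          const double dta_term = o.dist2 / dta2;
          if (dta_term >= best) break; // offsets sorted by distance
          double ev;
          if (subdivide == 1) {
            const int ii = i + o.di, jj = j + o.dj, kk = k + o.dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            ev = eval_at(ii, jj, kk);
          } else {
            bool ok;
            ev = eval_frac(i + o.di / (double)subdivide, j + o.dj / (double)subdivide,
                           k + o.dk / (double)subdivide, ok);
            if (!ok) continue;
          }
          const double dd = ev - R[v];
          const double val = dta_term + dd * dd / dd2;
          if (val < best) best = val;
        }
        gamma[v] = std::sqrt(best);
      }
  return gamma;
}
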