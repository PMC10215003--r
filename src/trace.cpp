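// Exact voxel ray tracing: radiological path lengths, cone-ray segment
// tables and divergent-beam TERMA on the voxel lattice.
#include "core.h"
using namespace Rcpp;
using namespace cccmr;

static Grid grid_args(const NumericVector& rho, const IntegerVector& dims,
                      const NumericVector& spacing, const NumericVector& origin) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.rho = REAL(rho);
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_radiological_path(NumericVector rho, IntegerVector dims,
                                    NumericVector spacing, NumericVector origin,
                                    NumericMatrix p0, NumericMatrix p1) {
  const Grid g = grid_args(rho, dims, spacing, origin);
  const int n = p0.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    const double a[3] = { p0(r, 0), p0(r, 1), p0(r, 2) };
    double d[3] = { p1(r, 0) - a[0], p1(r, 1) - a[1], p1(r, 2) - a[2] };
    const double len = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (len <= 0) { out[r] = 0.0; continue; }
    d[0] /= len; d[1] /= len; d[2] /= len;
    double acc = 0.0;
    traverse(g, a, d, len, [&](int vox, double tin, double tout) {
      acc += g.rho[vox] * (tout - tin);
      return true;
    });
    out[r] = acc;
  }
  return out;
}

// Per-segment cumulative geometric length L, radiological length p and running
// average density p/L along a ray from a voxel center to the grid boundary.
// [[Rcpp::export]]
NumericMatrix cpp_trace_cone_ray(NumericVector rho, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector start, NumericVector direction) {
  const Grid g = grid_args(rho, dims, spacing, origin);
  double d[3] = { direction[0], direction[1], direction[2] };
  renormalize(d);
  const double a[3] = { start[0], start[1], start[2] };
  std::vector<double> vox, li, Lc, pc;
  double p = 0.0;
  traverse(g, a, d, 1e30, [&](int v, double tin, double tout) {
    const double dl = tout - tin;
    p += g.rho[v] * dl;
    vox.push_back(v + 1); // 1-based for R
    li.push_back(dl);
    Lc.push_back(tout);
    pc.push_back(p);
    return true;
  });
  const int n = (int)vox.size();
  NumericMatrix out(n, 5);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = vox[i];
    out(i, 1) = li[i];
    out(i, 2) = Lc[i];
    out(i, 3) = pc[i];
    out(i, 4) = pc[i] / Lc[i];
  }
  colnames(out) = CharacterVector::create("voxel", "length", "L", "p", "rho_bar");
  return out;
}

// TERMA per voxel and energy for a divergent point source collimated to a
// rectangular field at the z = 0 surface plane. T_E = (mu/rho) E Phi_E with
// Phi_E = w_E exp(-(mu/rho) p) * SSD^2 / R^2 inside the field cone, 0 outside.
// [[Rcpp::export]]
NumericVector cpp_compute_terma(NumericVector rho, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                NumericVector src, double ssd, double half_x,
                                double half_y, NumericVector energies,
                                NumericVector weights, NumericVector tabE,
                                NumericVector tabMu, int n_sub) {
  const Grid g = grid_args(rho, dims, spacing, origin);
  FastTable Mu;
  Mu.init(tabE, tabMu);
  const int ne = energies.size();
  std::vector<double> mu(ne);
  for (int e = 0; e < ne; ++e) mu[e] = Mu.value(energies[e]);
  const size_t nvox = (size_t)g.nx * g.ny * g.nz;
  NumericVector out((R_xlen_t)(nvox * ne));
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, ne);
  for (int k = 0; k < g.nz; ++k) {
    for (int j = 0; j < g.ny; ++j) {
      for (int i = 0; i < g.nx; ++i) {
        const double c[3] = { g.ox + (i + 0.5) * g.sx,
                              g.oy + (j + 0.5) * g.sy,
                              g.oz + (k + 0.5) * g.sz };
        // fluence coverage: fraction of the voxel cross-section whose
        // projection onto the collimation plane z = 0 lies inside the field
        const double dz = c[2] - src[2];
        if (dz <= 0) continue;
        const double f = ssd / dz;
        double cov = 0.0;
        for (int a = 0; a < n_sub; ++a)
          for (int b = 0; b < n_sub; ++b) {
            const double px = c[0] + ((a + 0.5) / n_sub - 0.5) * g.sx;
            const double py = c[1] + ((b + 0.5) / n_sub - 0.5) * g.sy;
            const double xs = src[0] + (px - src[0]) * f;
            const double ys = src[1] + (py - src[1]) * f;
            if (std::fabs(xs) <= half_x && std::fabs(ys) <= half_y) cov += 1.0;
          }
        if (cov <= 0.0) continue;
        cov /= n_sub * n_sub;
        double d[3] = { c[0] - src[0], c[1] - src[1], dz };
        const double R2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        const double len = std::sqrt(R2);
        d[0] /= len; d[1] /= len; d[2] /= len;
        double p = 0.0;
        traverse(g, src.begin(), d, len, [&](int vox, double tin, double tout) {
          p += g.rho[vox] * (tout - tin);
          return true;
        });
        const size_t v = (size_t)i + g.nx * ((size_t)j + (size_t)g.ny * k);
        for (int e = 0; e < ne; ++e)
          out[v + nvox * e] = cov * weights[e] * mu[e] * energies[e] *
                              std::exp(-mu[e] * p) * ssd * ssd / R2;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
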