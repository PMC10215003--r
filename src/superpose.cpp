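// Collapsed-cone superposition with density scaling and average-density kernel
// lookup: for every TERMA source voxel and every cone direction, walk the ray
// to the grid boundary; each traversed voxel receives the differential kernel
// energy fraction between its entry and exit radiological radii, read from the
// cumulative cone table linearly interpolated in density at the running
// average density between source and segment exit.
#include "core.h"
using namespace Rcpp;
using namespace cccmr;

// cum layout: [bound (nr+1)] fastest, then energy, then direction, then density:
// index = ((irho * ndir + idir) * ne + ie) * (nr + 1) + ibound
// [[Rcpp::export]]
NumericMatrix cpp_superpose(NumericVector terma, NumericVector rho,
                            IntegerVector dims, NumericVector spacing,
                            NumericVector origin, NumericVector cum,
                            NumericVector rbounds, NumericVector densities,
                            NumericMatrix dirs, double thresh_rel) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.rho = REAL(rho);
  const size_t nvox = (size_t)g.nx * g.ny * g.nz;
  const int ne = terma.size() / nvox;
  const int ndir = dirs.nrow();
  const int nrho = densities.size();
  const int nb = rbounds.size(); // nr + 1
  const double* T = REAL(terma);
  const double* C = REAL(cum);
  const double* RB = REAL(rbounds);
  const double pmax = RB[nb - 1];
  NumericMatrix dose(nvox, ne);
  double* D = REAL(dose);

  // source threshold on the max TERMA over energies
  double tmax = 0.0;
  for (size_t v = 0; v < nvox; ++v)
    for (int e = 0; e < ne; ++e)
      tmax = std::max(tmax, T[v + nvox * e]);
  const double thr = thresh_rel * tmax;

  std::vector<double> dvec(3 * ndir);
  for (int d = 0; d < ndir; ++d) {
    dvec[3 * d] = dirs(d, 0); dvec[3 * d + 1] = dirs(d, 1); dvec[3 * d + 2] = dirs(d, 2);
  }
  const double drho = densities[1 > nrho - 1 ? 0 : 1] - densities[0];

  // linear-in-p evaluation of the cumulative table
  auto cval = [&](const double* base, int j, double fr) {
    return base[j] + fr * (base[j + 1] - base[j]);
  };

  for (int k = 0; k < g.nz; ++k) {
    for (int j = 0; j < g.ny; ++j) {
      for (int i = 0; i < g.nx; ++i) {
        const size_t s = (size_t)i + g.nx * ((size_t)j + (size_t)g.ny * k);
        double ts = 0.0;
        for (int e = 0; e < ne; ++e) ts = std::max(ts, T[s + nvox * e]);
        if (ts <= thr) continue;
        const double rho_s = g.rho[s];
        const double c0[3] = { g.ox + (i + 0.5) * g.sx,
                               g.oy + (j + 0.5) * g.sy,
                               g.oz + (k + 0.5) * g.sz };
        for (int d = 0; d < ndir; ++d) {
          const double* dv = &dvec[3 * d];
          double p_in = 0.0;
          int j_in = 0;
          double fr_in = 0.0;
          traverse(g, c0, dv, 1e30, [&](int v, double tin, double tout) {
            const double rv = g.rho[v];
            double p_out = p_in + rv * (tout - tin);
            if (p_out > pmax) p_out = pmax;
            // advance radial index (p monotone along the ray)
            int j_out = j_in;
            while (j_out < nb - 2 && p_out >= RB[j_out + 1]) ++j_out;
            const double w_out = RB[j_out + 1] - RB[j_out];
            const double fr_out = w_out > 0 ? (p_out - RB[j_out]) / w_out : 0.0;
            // density bracket at the running average density
            const double rho_bar = p_out / tout;
            int kd = 0;
            double wd = 0.0;
            if (nrho > 1) {
              const double x = (rho_bar - densities[0]) / drho;
              kd = (int)std::floor(x);
              if (kd < 0) kd = 0;
              if (kd > nrho - 2) kd = nrho - 2;
              wd = x - kd;
              if (wd < 0) wd = 0;
              if (wd > 1) wd = 1;
            }
            const size_t base_lo0 = ((size_t)kd * ndir + d) * ne;
            const size_t base_hi0 = ((size_t)std::min(kd + 1, nrho - 1) * ndir + d) * ne;
            const double inv_rv = 1.0 / rv;
            for (int e = 0; e < ne; ++e) {
              const double te = T[s + nvox * e];
              if (te <= 0) continue;
              const double* blo = C + (base_lo0 + e) * nb;
              const double fl = cval(blo, j_out, fr_out) - cval(blo, j_in, fr_in);
              double f;
              if (wd > 0) {
                const double* bhi = C + (base_hi0 + e) * nb;
                const double fh = cval(bhi, j_out, fr_out) - cval(bhi, j_in, fr_in);
                f = (1.0 - wd) * fl + wd * fh;
              } else {
                f = fl;
              }
              if (f != 0.0) D[v + nvox * e] += te * rho_s * f * inv_rv;
            }
            if (p_out >= pmax) return false; // kernel exhausted
            p_in = p_out; j_in = j_out; fr_in = fr_out;
            return true;
          });
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return dose;
}
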