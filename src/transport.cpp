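// Simplified condensed-history Monte Carlo engine: Compton/pair photon physics,
// CSDA electron stepping with exact gyration in a uniform magnetic field and
// optional Highland multiple scattering. Used both to generate spherical-grid
// energy deposition kernels and to produce reference dose grids in phantoms.
#include "core.h"
using namespace Rcpp;
using namespace cccmr;

namespace {

struct Settings {
  double p_cut;       // photon cutoff, MeV
  double e_cut_kin;   // electron kinetic cutoff, MeV
  double max_step;    // cm
  double min_step;    // cm
  double efrac_range; // step <= efrac_range * residual CSDA range
  bool ms_on;
  bool pair_on;
  double pe_local;    // photons below this undergo local absorption, MeV
  int nbatch;
};

Settings parse_settings(const List& s) {
  Settings st;
  st.p_cut = as<double>(s["photon_cutoff"]);
  st.e_cut_kin = as<double>(s["electron_cutoff_total"]) - ME;
  st.max_step = as<double>(s["max_step"]);
  st.min_step = as<double>(s["min_step"]);
  st.efrac_range = as<double>(s["efrac"]);
  st.ms_on = as<bool>(s["multiple_scattering"]);
  st.pair_on = as<bool>(s["pair_production"]);
  st.pe_local = as<double>(s["pe_local"]);
  st.nbatch = as<int>(s["n_batches"]);
  return st;
}

struct Field {
  double B;
  double bhat[3];
};

// --- scorers ---------------------------------------------------------------

// Spherical shell x polar x azimuth scorer in radiological units (r * rho).
struct SphereScorer {
  const std::vector<double>* rb; // radial bounds, g/cm2, length nr+1
  int nr, npol, naz;
  double rho, Rcm; // medium density and geometric sphere radius
  std::vector<double> cosb; // descending polar-bin cosine boundaries
  std::vector<double> batch, sum, sumsq, prim, effr, effc;
  double deposited = 0, escaped = 0;

  void init(const std::vector<double>& bounds, int np, int na, double rho_) {
    rb = &bounds;
    nr = (int)bounds.size() - 1; npol = np; naz = na;
    rho = rho_; Rcm = bounds.back() / rho_;
    cosb.resize(np + 1);
    for (int i = 0; i <= np; ++i) cosb[i] = std::cos(M_PI * i / np);
    const size_t n = (size_t)nr * npol * naz;
    batch.assign(n, 0.0); sum.assign(n, 0.0); sumsq.assign(n, 0.0);
    prim.assign(n, 0.0); effr.assign(n, 0.0); effc.assign(n, 0.0);
  }
  void deposit(const double pos[3], double e, bool primary) {
    if (e <= 0) return;
    const double rcm = std::sqrt(pos[0] * pos[0] + pos[1] * pos[1] + pos[2] * pos[2]);
    const double r = rcm * rho; // radiological radius
    if (r >= rb->back()) { escaped += e; return; }
    auto it = std::upper_bound(rb->begin(), rb->end(), r);
    int ir = (int)(it - rb->begin()) - 1;
    if (ir < 0) ir = 0;
    if (ir >= nr) ir = nr - 1;
    double ct = rcm > 0 ? pos[2] / rcm : 1.0;
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    // polar bin: binary search in the descending cosine boundaries
    int lo = 0, hi = npol;
    while (hi - lo > 1) {
      const int mid = (lo + hi) / 2;
      if (ct <= cosb[mid]) lo = mid; else hi = mid;
    }
    const int ip = lo;
    double ph = std::atan2(pos[1], pos[0]);
    if (ph < 0) ph += 2.0 * M_PI;
    int ia = (int)(ph / (2.0 * M_PI / naz));
    if (ia >= naz) ia = naz - 1;
    const size_t idx = (size_t)ir + (size_t)nr * (ip + (size_t)npol * ia);
    batch[idx] += e;
    deposited += e;
    if (primary) { prim[idx] += e; effr[idx] += e * r; effc[idx] += e * ct; }
  }
  void escape(double e) { escaped += e; }
  void end_batch() {
    for (size_t i = 0; i < batch.size(); ++i) {
      sum[i] += batch[i];
      sumsq[i] += batch[i] * batch[i];
      batch[i] = 0.0;
    }
  }
};

// Cartesian energy scorer.
struct GridScorer {
  Grid g;
  std::vector<double> batch, sum, sumsq;
  double deposited = 0, escaped = 0;
  void init(const Grid& grid) {
    g = grid;
    const size_t n = (size_t)g.nx * g.ny * g.nz;
    batch.assign(n, 0.0); sum.assign(n, 0.0); sumsq.assign(n, 0.0);
  }
  void deposit(const double pos[3], double e, bool) {
    if (e <= 0) return;
    if (!g.inside(pos)) { escaped += e; return; }
    batch[g.voxel(pos)] += e;
    deposited += e;
  }
  void escape(double e) { escaped += e; }
  void end_batch() {
    for (size_t i = 0; i < batch.size(); ++i) {
      sum[i] += batch[i];
      sumsq[i] += batch[i] * batch[i];
      batch[i] = 0.0;
    }
  }
};

// --- media -----------------------------------------------------------------

struct SphereMedium {
  double rho, Rcm;
  double rho_at(const double p[3]) const {
    return (p[0] * p[0] + p[1] * p[1] + p[2] * p[2] < Rcm * Rcm) ? rho : 0.0;
  }
};
struct GridMedium {
  const Grid* g;
  double rho_at(const double p[3]) const { return g->density(p); }
};

// --- charged particle transport --------------------------------------------
// Condensed-history stepping: continuous loss from the collision stopping
// power, exact gyration about the field axis (half-rotate / drift / half-
// rotate), optional Gaussian multiple scattering (Highland, X0 = 36.08 g/cm2).
// Outside the medium (vacuum) the particle gyrates without loss and is
// abandoned as escaped after three full turns fail to re-enter.
// Returns true when the particle ended by cutoff deposition (pos is then its
// stopping point), false if it escaped.
template <class MED, class SC>
bool transport_charged(double pos[3], double dir[3], double Ekin, int qsign,
                       bool primary, const Field& fl, const Settings& st,
                       const FastTable& S, const FastTable& Rcs,
                       const MED& med, SC& sc, RNG& rng) {
  double vac_len = 0.0;
  for (long guard = 0; guard < 4000000; ++guard) {
    if (Ekin <= st.e_cut_kin + 1e-12) { sc.deposit(pos, Ekin, primary); return true; }
    const double rho = med.rho_at(pos);
    const double Etot = Ekin + ME;
    const double p = std::sqrt(Ekin * (Ekin + TWO_ME));
    double rg = 0.0;
    double step = st.max_step;
    if (fl.B > 0) {
      rg = p / (2.99792458 * fl.B); // cm
      if (0.1 * rg < step) step = 0.1 * rg;
    }
    double dE = 0.0;
    if (rho > 0) {
      vac_len = 0.0;
      const double rres = Rcs.value(Ekin) / rho; // cm
      if (st.efrac_range * rres < step) step = st.efrac_range * rres;
      if (step < st.min_step) step = st.min_step;
      dE = S.value(Ekin) * rho * step;
      if (dE > Ekin - st.e_cut_kin) {
        step *= (Ekin - st.e_cut_kin) / dE;
        dE = Ekin - st.e_cut_kin;
      }
    } else {
      if (fl.B <= 0) { sc.escape(Ekin); return false; }
      vac_len += step;
      if (vac_len > 6.0 * M_PI * rg) { sc.escape(Ekin); return false; }
    }
    if (fl.B > 0) {
      const double half = -qsign * 0.5 * step / rg;
      const double ch = std::cos(half), sh = std::sin(half);
      rotate_about_cached(dir, fl.bhat, ch, sh);
      if (dE > 0) {
        const double mid[3] = { pos[0] + 0.5 * step * dir[0],
                                pos[1] + 0.5 * step * dir[1],
                                pos[2] + 0.5 * step * dir[2] };
        sc.deposit(mid, dE, primary);
      }
      pos[0] += step * dir[0]; pos[1] += step * dir[1]; pos[2] += step * dir[2];
      rotate_about_cached(dir, fl.bhat, ch, sh);
    } else {
      if (dE > 0) {
        const double mid[3] = { pos[0] + 0.5 * step * dir[0],
                                pos[1] + 0.5 * step * dir[1],
                                pos[2] + 0.5 * step * dir[2] };
        sc.deposit(mid, dE, primary);
      }
      pos[0] += step * dir[0]; pos[1] += step * dir[1]; pos[2] += step * dir[2];
    }
    if (st.ms_on && rho > 0) {
      const double t = rho * step / X0_WATER;
      double fac = 1.0 + 0.038 * std::log(t);
      if (fac < 0.25) fac = 0.25;
      const double th0 = 13.6 / (p * p / Etot) * std::sqrt(t) * fac;
      deflect_small_angle(dir, th0 * rng.gauss(), th0 * rng.gauss());
    }
    Ekin -= dE;
  }
  sc.escape(Ekin); // unreachable in practice
  return false;
}

// --- photon interactions ----------------------------------------------------

struct Secondary { double E; double dir[3]; int kind; }; // 0 photon, 1 e-, 2 e+
struct EventOut {
  double local_dep = 0.0;
  int n = 0;
  Secondary sec[4];
  void push(double E, const double d[3], int kind) {
    sec[n].E = E; sec[n].kind = kind;
    sec[n].dir[0] = d[0]; sec[n].dir[1] = d[1]; sec[n].dir[2] = d[2];
    ++n;
  }
};

void sample_interaction(double E, const double dir[3], RNG& rng,
                        const Settings& st, const FastTable& Mu, EventOut& ev) {
  ev.local_dep = 0.0; ev.n = 0;
  const double mu_tab = Mu.value(E);
  const double pc = std::min(1.0, mu_kn_over_rho(E) / mu_tab);
  const double u = rng.unif();
  if (u < pc) {
    double eps, cost;
    sample_kn(E, rng, eps, cost);
    const double Es = eps * E;
    const double T = E - Es;
    const double phi = 2.0 * M_PI * rng.unif();
    const double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
    const double lp[3] = { sint * std::cos(phi), sint * std::sin(phi), cost };
    double dphot[3];
    rotate_to_frame(dir, lp, dphot);
    // electron from momentum conservation (photon momentum = E in MeV/c)
    double pe[3] = { E * dir[0] - Es * dphot[0],
                     E * dir[1] - Es * dphot[1],
                     E * dir[2] - Es * dphot[2] };
    const double pn = std::sqrt(pe[0] * pe[0] + pe[1] * pe[1] + pe[2] * pe[2]);
    if (pn > 1e-12) { pe[0] /= pn; pe[1] /= pn; pe[2] /= pn; }
    else { pe[0] = dir[0]; pe[1] = dir[1]; pe[2] = dir[2]; }
    ev.push(T, pe, 1);
    if (Es > st.p_cut) ev.push(Es, dphot, 0);
    else ev.local_dep += Es;
  } else if (st.pair_on && E > TWO_ME) {
    const double Ek = E - TWO_ME;
    const double T1 = rng.unif() * Ek;
    ev.push(T1, dir, 1);
    ev.push(Ek - T1, dir, 2);
  } else {
    if (E >= st.pe_local) ev.push(E, dir, 1);
    else ev.local_dep += E;
  }
}

struct PhotonRec { double pos[3], dir[3], E; bool primary_electrons; };

// Process the secondaries of one interaction: transport charged particles,
// annihilate stopped positrons, push surviving photons onto the stack.
template <class MED, class SC>
void handle_event(const EventOut& ev, const double pos[3], bool primary,
                  const Field& fl, const Settings& st,
                  const FastTable& S, const FastTable& Rcs,
                  const MED& med, SC& sc, RNG& rng,
                  std::vector<PhotonRec>& stack, double& created, double& sunk) {
  if (ev.local_dep > 0) sc.deposit(pos, ev.local_dep, primary);
  for (int i = 0; i < ev.n; ++i) {
    const Secondary& s2 = ev.sec[i];
    if (s2.kind == 0) {
      PhotonRec pr;
      pr.pos[0] = pos[0]; pr.pos[1] = pos[1]; pr.pos[2] = pos[2];
      pr.dir[0] = s2.dir[0]; pr.dir[1] = s2.dir[1]; pr.dir[2] = s2.dir[2];
      pr.E = s2.E; pr.primary_electrons = false;
      stack.push_back(pr);
    } else {
      double ppos[3] = { pos[0], pos[1], pos[2] };
      double pdir[3] = { s2.dir[0], s2.dir[1], s2.dir[2] };
      const int q = (s2.kind == 2) ? +1 : -1;
      if (s2.kind == 2) sunk += TWO_ME; // rest mass bound at pair creation
      const bool stopped = transport_charged(ppos, pdir, s2.E, q, primary,
                                             fl, st, S, Rcs, med, sc, rng);
      if (s2.kind == 2 && stopped) {
        // annihilation at rest: two isotropic back-to-back 0.511 MeV photons
        created += TWO_ME;
        const double ct = 2.0 * rng.unif() - 1.0;
        const double stt = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        const double phi = 2.0 * M_PI * rng.unif();
        double w[3] = { stt * std::cos(phi), stt * std::sin(phi), ct };
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          PhotonRec pr;
          pr.pos[0] = ppos[0]; pr.pos[1] = ppos[1]; pr.pos[2] = ppos[2];
          pr.dir[0] = sgn * w[0]; pr.dir[1] = sgn * w[1]; pr.dir[2] = sgn * w[2];
          pr.E = ME; pr.primary_electrons = false;
          stack.push_back(pr);
        }
      }
    }
  }
}

// Analog photon transport in the uniform sphere: exponential free paths.
template <class SC>
void transport_photons_sphere(std::vector<PhotonRec>& stack, const SphereMedium& med,
                              const Field& fl, const Settings& st,
                              const FastTable& Mu, const FastTable& S,
                              const FastTable& Rcs, SC& sc, RNG& rng,
                              double& created, double& sunk) {
  while (!stack.empty()) {
    PhotonRec ph = stack.back();
    stack.pop_back();
    for (;;) {
      if (ph.E <= st.p_cut) { sc.deposit(ph.pos, ph.E, false); break; }
      const double mu = Mu.value(ph.E) * med.rho; // 1/cm
      const double s = -std::log(rng.unif_pos()) / mu;
      ph.pos[0] += s * ph.dir[0]; ph.pos[1] += s * ph.dir[1]; ph.pos[2] += s * ph.dir[2];
      if (ph.pos[0] * ph.pos[0] + ph.pos[1] * ph.pos[1] + ph.pos[2] * ph.pos[2] >=
          med.Rcm * med.Rcm) { sc.escape(ph.E); break; }
      EventOut ev;
      sample_interaction(ph.E, ph.dir, rng, st, Mu, ev);
      handle_event(ev, ph.pos, false, fl, st, S, Rcs, med, sc, rng, stack, created,
                   sunk);
      break;
    }
  }
}

// Woodcock (delta) tracking in a voxel grid.
template <class SC>
void transport_photons_grid(std::vector<PhotonRec>& stack, const GridMedium& med,
                            double rho_max, const Field& fl, const Settings& st,
                            const FastTable& Mu, const FastTable& S,
                            const FastTable& Rcs, SC& sc, RNG& rng,
                            double& created, double& sunk) {
  const Grid& g = *med.g;
  while (!stack.empty()) {
    PhotonRec ph = stack.back();
    stack.pop_back();
    if (!g.inside(ph.pos)) {
      double t0, t1;
      if (!clip_to_box(g, ph.pos, ph.dir, 1e30, t0, t1) || t0 < 0) {
        sc.escape(ph.E);
        continue;
      }
      const double t = t0 + 1e-9;
      ph.pos[0] += t * ph.dir[0]; ph.pos[1] += t * ph.dir[1]; ph.pos[2] += t * ph.dir[2];
    }
    for (;;) {
      if (ph.E <= st.p_cut) { sc.deposit(ph.pos, ph.E, false); break; }
      const double mu_max = Mu.value(ph.E) * rho_max;
      const double s = -std::log(rng.unif_pos()) / mu_max;
      ph.pos[0] += s * ph.dir[0]; ph.pos[1] += s * ph.dir[1]; ph.pos[2] += s * ph.dir[2];
      if (!g.inside(ph.pos)) { sc.escape(ph.E); break; }
      if (rng.unif() * rho_max >= g.rho[g.voxel(ph.pos)]) continue; // virtual
      EventOut ev;
      sample_interaction(ph.E, ph.dir, rng, st, Mu, ev);
      handle_event(ev, ph.pos, ph.primary_electrons, fl, st, S, Rcs, med, sc, rng,
                   stack, created, sunk);
      break;
    }
  }
}

Field make_field(double B, const NumericVector& bdir) {
  Field f;
  f.B = B;
  double n = std::sqrt(bdir[0] * bdir[0] + bdir[1] * bdir[1] + bdir[2] * bdir[2]);
  if (n <= 0) n = 1.0;
  f.bhat[0] = bdir[0] / n; f.bhat[1] = bdir[1] / n; f.bhat[2] = bdir[2] / n;
  return f;
}

List batch_stats(const std::vector<double>& sum, const std::vector<double>& sumsq,
                 int nb) {
  const size_t n = sum.size();
  NumericVector mean(n), rse(n);
  for (size_t i = 0; i < n; ++i) {
    const double m = sum[i] / nb;
    mean[i] = sum[i];
    if (m > 0 && nb > 1) {
      double var = (sumsq[i] / nb - m * m) * nb / (nb - 1.0);
      if (var < 0) var = 0;
      rse[i] = std::sqrt(var / nb) / m;
    } else {
      rse[i] = 0.0;
    }
  }
  return List::create(_["sum"] = mean, _["rse"] = rse);
}

} // namespace

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double energy, int n, double seed) {
  NumericMatrix out(n, 4); // E_scattered, cos_theta_photon, T_electron, cos_theta_electron
  const double zhat[3] = { 0.0, 0.0, 1.0 };
  for (int i = 0; i < n; ++i) {
    RNG rng((uint64_t)seed, (uint64_t)i);
    double eps, cost;
    sample_kn(energy, rng, eps, cost);
    const double Es = eps * energy;
    const double phi = 2.0 * M_PI * rng.unif();
    const double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
    const double lp[3] = { sint * std::cos(phi), sint * std::sin(phi), cost };
    double dp[3];
    rotate_to_frame(zhat, lp, dp);
    double pe[3] = { -Es * dp[0], -Es * dp[1], energy - Es * dp[2] };
    const double pn = std::sqrt(pe[0] * pe[0] + pe[1] * pe[1] + pe[2] * pe[2]);
    out(i, 0) = Es;
    out(i, 1) = cost;
    out(i, 2) = energy - Es;
    out(i, 3) = pn > 0 ? pe[2] / pn : 1.0;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_electron_trajectory(double energy, NumericVector pos0, NumericVector dir0,
                             int qsign, double B, NumericVector bdir, double rho,
                             double step_cm, bool use_stopping, bool use_ms,
                             double e_cut_kin, int max_steps, double seed,
                             NumericVector tabE, NumericVector tabS,
                             NumericVector tabR) {
  FastTable S, Rcs;
  S.init(tabE, tabS);
  Rcs.init(tabE, tabR);
  Field fl = make_field(B, bdir);
  RNG rng((uint64_t)seed, 0);
  double pos[3] = { pos0[0], pos0[1], pos0[2] };
  double dir[3] = { dir0[0], dir0[1], dir0[2] };
  renormalize(dir);
  double Ekin = energy, path = 0.0, dep = 0.0;
  NumericMatrix traj(max_steps + 1, 3);
  int nrec = 0;
  traj(0, 0) = pos[0]; traj(0, 1) = pos[1]; traj(0, 2) = pos[2];
  ++nrec;
  for (int it = 0; it < max_steps; ++it) {
    if (Ekin <= e_cut_kin + 1e-12) { dep += Ekin; break; }
    const double p = std::sqrt(Ekin * (Ekin + TWO_ME));
    const double Etot = Ekin + ME;
    double step = step_cm;
    double rg = 0.0;
    if (B > 0) rg = p / (2.99792458 * B);
    double dE = 0.0;
    if (use_stopping && rho > 0) {
      dE = S.value(Ekin) * rho * step;
      if (dE > Ekin - e_cut_kin) {
        step *= (Ekin - e_cut_kin) / dE;
        dE = Ekin - e_cut_kin;
      }
    }
    if (B > 0) rotate_about(dir, fl.bhat, -qsign * 0.5 * step / rg);
    pos[0] += step * dir[0]; pos[1] += step * dir[1]; pos[2] += step * dir[2];
    if (B > 0) rotate_about(dir, fl.bhat, -qsign * 0.5 * step / rg);
    if (use_ms && rho > 0) {
      const double t = rho * step / X0_WATER;
      double fac = 1.0 + 0.038 * std::log(t);
      if (fac < 0.25) fac = 0.25;
      const double th0 = 13.6 / (p * p / Etot) * std::sqrt(t) * fac;
      const double thx = th0 * rng.gauss(), thy = th0 * rng.gauss();
      const double th = std::sqrt(thx * thx + thy * thy);
      const double ph = std::atan2(thy, thx);
      const double local[3] = { std::sin(th) * std::cos(ph),
                                std::sin(th) * std::sin(ph), std::cos(th) };
      double nd[3];
      rotate_to_frame(dir, local, nd);
      dir[0] = nd[0]; dir[1] = nd[1]; dir[2] = nd[2];
      renormalize(dir);
    }
    path += step;
    dep += dE;
    Ekin -= dE;
    traj(nrec, 0) = pos[0]; traj(nrec, 1) = pos[1]; traj(nrec, 2) = pos[2];
    ++nrec;
  }
  return List::create(_["positions"] = traj(Range(0, nrec - 1), _),
                      _["path_length"] = path,
                      _["deposited"] = dep,
                      _["residual_energy"] = Ekin);
}

// [[Rcpp::export]]
List cpp_generate_edk(double energy, double rho, double B, NumericVector bdir,
                      NumericVector radial_bounds, int npol, int naz,
                      double n_hist, List settings, double seed,
                      NumericVector tabE, NumericVector tabMu,
                      NumericVector tabS, NumericVector tabR) {
  const Settings st = parse_settings(settings);
  FastTable Mu, S, Rcs;
  Mu.init(tabE, tabMu);
  S.init(tabE, tabS);
  Rcs.init(tabE, tabR);
  const Field fl = make_field(B, bdir);
  std::vector<double> rb(radial_bounds.begin(), radial_bounds.end());
  SphereScorer sc;
  sc.init(rb, npol, naz, rho);
  SphereMedium med{ rho, sc.Rcm };
  const double zhat[3] = { 0.0, 0.0, 1.0 };
  const uint64_t NH = (uint64_t)n_hist;
  const int nb = st.nbatch;
  double created = 0.0, sunk = 0.0;
  std::vector<PhotonRec> stack;
  stack.reserve(16);
  uint64_t h = 0;
  for (int b = 0; b < nb; ++b) {
    const uint64_t hb = NH / nb + (b < (int)(NH % nb) ? 1 : 0);
    for (uint64_t i = 0; i < hb; ++i, ++h) {
      RNG rng((uint64_t)seed, h);
      EventOut ev;
      sample_interaction(energy, zhat, rng, st, Mu, ev);
      const double origin[3] = { 0.0, 0.0, 0.0 };
      stack.clear();
      handle_event(ev, origin, true, fl, st, S, Rcs, med, sc, rng, stack, created,
                   sunk);
      transport_photons_sphere(stack, med, fl, st, Mu, S, Rcs, sc, rng, created, sunk);
    }
    sc.end_batch();
    Rcpp::checkUserInterrupt();
  }
  List vs = batch_stats(sc.sum, sc.sumsq, nb);
  return List::create(_["energy_sum"] = vs["sum"], _["rse"] = vs["rse"],
                      _["primary_sum"] = wrap(sc.prim),
                      _["eff_r_sum"] = wrap(sc.effr),
                      _["eff_cos_sum"] = wrap(sc.effc),
                      _["deposited"] = sc.deposited, _["escaped"] = sc.escaped,
                      _["created"] = created, _["mass_sunk"] = sunk,
                      _["n_histories"] = (double)NH);
}

static Grid grid_from_args(const NumericVector& rho, const IntegerVector& dims,
                           const NumericVector& spacing, const NumericVector& origin) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.rho = REAL(rho);
  return g;
}

// [[Rcpp::export]]
List cpp_simulate_dose(NumericVector rho, IntegerVector dims, NumericVector spacing,
                       NumericVector origin, NumericVector src, double half_x,
                       double half_y, NumericVector spec_E, NumericVector spec_w,
                       double B, NumericVector bdir, double n_hist, List settings,
                       double seed, NumericVector tabE, NumericVector tabMu,
                       NumericVector tabS, NumericVector tabR) {
  const Settings st = parse_settings(settings);
  FastTable Mu, S, Rcs;
  Mu.init(tabE, tabMu);
  S.init(tabE, tabS);
  Rcs.init(tabE, tabR);
  const Field fl = make_field(B, bdir);
  const Grid g = grid_from_args(rho, dims, spacing, origin);
  GridScorer sc;
  sc.init(g);
  GridMedium med{ &g };
  double rho_max = 0.0;
  const size_t nvox = (size_t)g.nx * g.ny * g.nz;
  for (size_t i = 0; i < nvox; ++i) rho_max = std::max(rho_max, g.rho[i]);
  const int ne = spec_E.size();
  std::vector<double> cw(ne);
  double acc = 0.0;
  for (int i = 0; i < ne; ++i) { acc += spec_w[i]; cw[i] = acc; }
  for (int i = 0; i < ne; ++i) cw[i] /= acc;
  const uint64_t NH = (uint64_t)n_hist;
  const int nb = st.nbatch;
  double e_in = 0.0, created = 0.0, sunk = 0.0;
  std::vector<PhotonRec> stack;
  stack.reserve(16);
  uint64_t h = 0;
  for (int b = 0; b < nb; ++b) {
    const uint64_t hb = NH / nb + (b < (int)(NH % nb) ? 1 : 0);
    for (uint64_t i = 0; i < hb; ++i, ++h) {
      RNG rng((uint64_t)seed, h);
      const double u = rng.unif();
      const int ei = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
      const double E = spec_E[std::min(ei, ne - 1)];
      const double tx = (2.0 * rng.unif() - 1.0) * half_x;
      const double ty = (2.0 * rng.unif() - 1.0) * half_y;
      double d[3] = { tx - src[0], ty - src[1], 0.0 - src[2] };
      renormalize(d);
      PhotonRec pr;
      pr.pos[0] = src[0]; pr.pos[1] = src[1]; pr.pos[2] = src[2];
      pr.dir[0] = d[0]; pr.dir[1] = d[1]; pr.dir[2] = d[2];
      pr.E = E; pr.primary_electrons = true;
      e_in += E;
      stack.clear();
      stack.push_back(pr);
      transport_photons_grid(stack, med, rho_max, fl, st, Mu, S, Rcs, sc, rng,
                             created, sunk);
    }
    sc.end_batch();
    Rcpp::checkUserInterrupt();
  }
  List vs = batch_stats(sc.sum, sc.sumsq, nb);
  return List::create(_["energy_sum"] = vs["sum"], _["rse"] = vs["rse"],
                      _["energy_in"] = e_in, _["deposited"] = sc.deposited,
                      _["escaped"] = sc.escaped, _["created"] = created,
                      _["mass_sunk"] = sunk, _["n_histories"] = (double)NH);
}

// [[Rcpp::export]]
List cpp_simulate_point_interaction(NumericVector rho, IntegerVector dims,
                                    NumericVector spacing, NumericVector origin,
                                    NumericVector point, double energy, double B,
                                    NumericVector bdir, double n_hist, List settings,
                                    double seed, NumericVector tabE,
                                    NumericVector tabMu, NumericVector tabS,
                                    NumericVector tabR) {
  const Settings st = parse_settings(settings);
  FastTable Mu, S, Rcs;
  Mu.init(tabE, tabMu);
  S.init(tabE, tabS);
  Rcs.init(tabE, tabR);
  const Field fl = make_field(B, bdir);
  const Grid g = grid_from_args(rho, dims, spacing, origin);
  GridScorer sc;
  sc.init(g);
  GridMedium med{ &g };
  double rho_max = 0.0;
  const size_t nvox = (size_t)g.nx * g.ny * g.nz;
  for (size_t i = 0; i < nvox; ++i) rho_max = std::max(rho_max, g.rho[i]);
  const double zhat[3] = { 0.0, 0.0, 1.0 };
  const uint64_t NH = (uint64_t)n_hist;
  const int nb = st.nbatch;
  double created = 0.0, sunk = 0.0;
  std::vector<PhotonRec> stack;
  stack.reserve(16);
  uint64_t h = 0;
  for (int b = 0; b < nb; ++b) {
    const uint64_t hb = NH / nb + (b < (int)(NH % nb) ? 1 : 0);
    for (uint64_t i = 0; i < hb; ++i, ++h) {
      RNG rng((uint64_t)seed, h);
      EventOut ev;
      sample_interaction(energy, zhat, rng, st, Mu, ev);
      const double p0[3] = { point[0], point[1], point[2] };
      stack.clear();
      handle_event(ev, p0, true, fl, st, S, Rcs, med, sc, rng, stack, created, sunk);
      transport_photons_grid(stack, med, rho_max, fl, st, Mu, S, Rcs, sc, rng,
                             created, sunk);
    }
    sc.end_batch();
    Rcpp::checkUserInterrupt();
  }
  List vs = batch_stats(sc.sum, sc.sumsq, nb);
  return List::create(_["energy_sum"] = vs["sum"], _["rse"] = vs["rse"],
                      _["deposited"] = sc.deposited, _["escaped"] = sc.escaped,
                      _["created"] = created, _["mass_sunk"] = sunk,
                      _["n_histories"] = (double)NH);
}

// [[Rcpp::export]]
double cpp_kn_mu_over_rho(double energy) { return mu_kn_over_rho(energy); }
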