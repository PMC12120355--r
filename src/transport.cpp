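// Monte Carlo kernels: X-ray transport (Klein-Nishina Compton +
// photoelectric), electron continuous-slowing-down stepping with
// Frank-Tamm Cherenkov generation, and optical photon tracing
// (Henyey-Greenstein scattering, Fresnel tissue-air boundaries) through a
// voxelized heterogeneous grid. All randomness comes from R's RNG so that
// set.seed() governs reproducibility end to end.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double MEC2 = 0.511;            // electron rest energy, MeV
static const double INV_ALPHA = 137.035999;  // 1 / fine-structure constant

struct Grid {
  const int *tissue;
  const double *density;
  int nx, ny, nz;
  double sx, sy, sz;
  double lox, loy, loz;  // lower corner (voxel faces), mm
  double hix, hiy, hiz;

  inline bool voxel_of(const double *p, int &ix, int &iy, int &iz) const {
    ix = (int)std::floor((p[0] - lox) / sx);
    iy = (int)std::floor((p[1] - loy) / sy);
    iz = (int)std::floor((p[2] - loz) / sz);
    return ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz;
  }
  inline int idx(int ix, int iy, int iz) const {
    return ix + nx * (iy + ny * iz);
  }
  inline bool inside(int ix, int iy, int iz) const {
    return ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz;
  }
};

static Grid make_grid(const IntegerVector &tissue, const NumericVector &density,
                      const IntegerVector &dims, const NumericVector &spacing,
                      const NumericVector &origin) {
  Grid g;
  g.tissue = tissue.begin();
  g.density = density.begin();
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.lox = origin[0] - 0.5 * g.sx;
  g.loy = origin[1] - 0.5 * g.sy;
  g.loz = origin[2] - 0.5 * g.sz;
  g.hix = g.lox + g.nx * g.sx;
  g.hiy = g.loy + g.ny * g.sy;
  g.hiz = g.loz + g.nz * g.sz;
  return g;
}

// linear interpolation on an ascending grid, clamped at the ends
static inline double interp1(const double *xg, const double *yg, int n, double x) {
  if (x <= xg[0]) return yg[0];
  if (x >= xg[n - 1]) return yg[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (xg[mid] <= x) lo = mid; else hi = mid;
  }
  double w = (x - xg[lo]) / (xg[lo + 1] - xg[lo]);
  return yg[lo] * (1 - w) + yg[lo + 1] * w;
}

// rotate unit vector d by polar angle (cos ct) and azimuth phi (MCML style)
static inline void deflect(double *d, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  if (std::fabs(uz) > 0.999999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    d[0] = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    d[1] = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    d[2] = -st * cp * den + uz * ct;
  }
  double norm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= norm; d[1] /= norm; d[2] /= norm;
}

// Klein-Nishina sampling of the Compton scattering cosine by rejection
static inline double sample_kn_cosine(double energy) {
  double k = energy / MEC2;
  for (;;) {
    double mu = 2.0 * unif_rand() - 1.0;
    double r = 1.0 / (1.0 + k * (1.0 - mu));       // E'/E
    double f = r + r * r * r - r * r * (1.0 - mu * mu);
    if (2.0 * unif_rand() < f) return mu;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(int n, double energy) {
  NumericMatrix out(n, 3);  // cos_theta, E', E_e
  double k = energy / MEC2;
  for (int i = 0; i < n; i++) {
    double mu = sample_kn_cosine(energy);
    double ep = energy / (1.0 + k * (1.0 - mu));
    out(i, 0) = mu;
    out(i, 1) = ep;
    out(i, 2) = energy - ep;
  }
  return out;
}

// ray-box entry: advance p to the grid boundary; false if the ray misses
static bool advance_to_grid(const Grid &g, double *p, const double *d) {
  double t0 = 0.0, t1 = 1e30;
  const double lo[3] = {g.lox, g.loy, g.loz};
  const double hi[3] = {g.hix, g.hiy, g.hiz};
  for (int a = 0; a < 3; a++) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p[a] <= lo[a] || p[a] >= hi[a]) return false;
    } else {
      double ta = (lo[a] - p[a]) / d[a];
      double tb = (hi[a] - p[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t1 <= t0) return false;
  if (t0 > 0) {
    double eps = 1e-9 * (g.sx + g.sy + g.sz);
    for (int a = 0; a < 3; a++) p[a] += (t0 + eps) * d[a];
    int ix, iy, iz;
    if (!g.voxel_of(p, ix, iy, iz)) return false;
  }
  return true;
}

struct DDA {
  int ix, iy, iz;
  int stepx, stepy, stepz;
  double tmaxx, tmaxy, tmaxz;
  double tdx, tdy, tdz;
  double t;  // distance travelled so far
};

static void dda_init(const Grid &g, const double *p, const double *d, DDA &s) {
  g.voxel_of(p, s.ix, s.iy, s.iz);
  s.t = 0.0;
  const double sp[3] = {g.sx, g.sy, g.sz};
  const double lo[3] = {g.lox, g.loy, g.loz};
  int iv[3] = {s.ix, s.iy, s.iz};
  double tmax[3], td[3];
  int st[3];
  for (int a = 0; a < 3; a++) {
    if (d[a] > 1e-12) {
      st[a] = 1;
      td[a] = sp[a] / d[a];
      tmax[a] = (lo[a] + (iv[a] + 1) * sp[a] - p[a]) / d[a];
    } else if (d[a] < -1e-12) {
      st[a] = -1;
      td[a] = -sp[a] / d[a];
      tmax[a] = (lo[a] + iv[a] * sp[a] - p[a]) / d[a];
    } else {
      st[a] = 0;
      td[a] = 1e30;
      tmax[a] = 1e30;
    }
  }
  s.stepx = st[0]; s.stepy = st[1]; s.stepz = st[2];
  s.tdx = td[0]; s.tdy = td[1]; s.tdz = td[2];
  s.tmaxx = tmax[0]; s.tmaxy = tmax[1]; s.tmaxz = tmax[2];
}

// ----------------------------------------------------------------------
// Cherenkov emission helpers

static inline double beta_of(double E) {
  double g = E / MEC2 + 1.0;
  return std::sqrt(std::max(0.0, 1.0 - 1.0 / (g * g)));
}

// expected Cherenkov photons per mm in [l1, l2] nm
static inline double ft_yield(double beta, double n, double z,
                              double l1, double l2) {
  double bn = beta * n;
  if (bn <= 1.0) return 0.0;
  return 2.0 * M_PI * z * z / INV_ALPHA * (1.0 - 1.0 / (bn * bn)) *
         (1.0 / l1 - 1.0 / l2) * 1e6;
}

struct PhotonBank {
  std::vector<double> px, py, pz, dx, dy, dz, lam;
  std::vector<int> vox;
};

struct EmitOpts {
  double z_charge, l1, l2, step, e_cutoff;
  int birth_filter;   // tissue code; -1 = keep all
  double keep_prob;
  double bank_cap;    // max photons kept in the bank
  bool analog;        // analog Poisson emission vs expected-value scoring
};

// transport one electron; returns energy escaping the grid
static double run_electron(const Grid &g, double *p, double *d, double E,
                           const double *eg, int ne,
                           const double *stop_mat,  // ne x T
                           const double *ref_density,
                           const double *n_tissue,
                           const EmitOpts &o,
                           double *deposit, double *emission,
                           double &n_emitted, PhotonBank *bank) {
  while (E > 0) {
    int ix, iy, iz;
    if (!g.voxel_of(p, ix, iy, iz)) return E;  // escaped with remaining energy
    int v = g.idx(ix, iy, iz);
    int t = g.tissue[v];
    double rho = g.density[v];
    double S = interp1(eg, stop_mat + (size_t)ne * t, ne, E) *
               (ref_density[t] > 0 ? rho / ref_density[t] : 0.0);
    double step = o.step;
    double dE;
    if (S <= 1e-12) {
      dE = 0.0;  // effectively vacuum: drift through
    } else {
      dE = S * step;
      if (dE >= E) {            // final partial step
        step = E / S;
        dE = E;
      }
    }
    double Emid = E - 0.5 * dE;
    double beta = beta_of(Emid);
    double n = n_tissue[t];
    double mx = p[0] + 0.5 * step * d[0];
    double my = p[1] + 0.5 * step * d[1];
    double mz = p[2] + 0.5 * step * d[2];
    if (beta * n > 1.0) {
      double y = ft_yield(beta, n, o.z_charge, o.l1, o.l2) * step;
      int mix, miy, miz;
      bool mid_in = g.voxel_of(&mx, mix, miy, miz);
      // (guard: midpoint off-grid can only happen on the last sliver)
      if (mid_in) {
        int mv = g.idx(mix, miy, miz);
        int mt = g.tissue[mv];
        if (n_tissue[mt] * beta > 1.0) {  // emission decided in the midpoint voxel
          if (o.analog) {
            int npho = (int)R::rpois(y);
            if (npho > 0) {
              n_emitted += npho;
              emission[mv] += npho;
              double ct = 1.0 / (beta * n_tissue[mt]);
              for (int q = 0; q < npho; q++) {
                if (!bank) continue;
                if (o.birth_filter >= 0 && mt != o.birth_filter) continue;
                if (o.keep_prob < 1.0 && unif_rand() >= o.keep_prob) continue;
                if ((double)bank->lam.size() >= o.bank_cap) continue;
                double u = unif_rand();
                double invl = 1.0 / o.l1 - u * (1.0 / o.l1 - 1.0 / o.l2);
                double lam = 1.0 / invl;
                double nd[3] = {d[0], d[1], d[2]};
                deflect(nd, ct, 2.0 * M_PI * unif_rand());
                bank->px.push_back(mx); bank->py.push_back(my);
                bank->pz.push_back(mz);
                bank->dx.push_back(nd[0]); bank->dy.push_back(nd[1]);
                bank->dz.push_back(nd[2]);
                bank->lam.push_back(lam);
                bank->vox.push_back(mv);
              }
            }
          } else {
            n_emitted += y;
            emission[mv] += y;
          }
        }
      }
    }
    // deposit at the midpoint voxel (step << voxel size)
    {
      int mix, miy, miz;
      if (g.voxel_of(&mx, mix, miy, miz)) {
        deposit[g.idx(mix, miy, miz)] += dE;
      } else {
        deposit[v] += dE;
      }
    }
    p[0] += step * d[0]; p[1] += step * d[1]; p[2] += step * d[2];
    E -= dE;
    if (dE == 0.0) {
      // vacuum drift: jump a voxel-scale distance to avoid tiny-step loops
      double jump = std::min(std::min(g.sx, g.sy), g.sz);
      p[0] += jump * d[0]; p[1] += jump * d[1]; p[2] += jump * d[2];
    }
    if (E <= o.e_cutoff && E > 0) {
      int jx, jy, jz;
      if (g.voxel_of(p, jx, jy, jz)) {
        deposit[g.idx(jx, jy, jz)] += E;
        return 0.0;
      }
      return E;
    }
  }
  return 0.0;
}

struct XRayOpts {
  double cutoff;
};

// transport one X-ray photon; electrons are handed to `electron_sink`
// (fused mode) or stored in a bank (modular mode)
template <typename ElectronSink>
static void run_xray(const Grid &g, double *p, double *d, double E,
                     const double *eg, int ne,
                     const double *muc_mat, const double *mupe_mat,
                     const double *ref_density,
                     const XRayOpts &o, double *deposit,
                     double &edep, double &eesc, ElectronSink sink) {
  int T_try = 0;
  while (E > 0 && ++T_try < 100000) {
    int ix, iy, iz;
    if (!g.voxel_of(p, ix, iy, iz)) {
      if (!advance_to_grid(g, p, d)) { eesc += E; return; }
      if (!g.voxel_of(p, ix, iy, iz)) { eesc += E; return; }
    }
    // per-tissue attenuation at the current energy
    double muc[16], mupe[16];
    for (int nt = 0; nt < 7; nt++) {
      muc[nt] = interp1(eg, muc_mat + (size_t)ne * nt, ne, E);
      mupe[nt] = interp1(eg, mupe_mat + (size_t)ne * nt, ne, E);
    }
    double tau = -std::log(unif_rand());
    DDA s;
    dda_init(g, p, d, s);
    bool interacted = false;
    double tacc = 0.0;
    int vcur = -1;
    while (true) {
      if (!g.inside(s.ix, s.iy, s.iz)) break;
      vcur = g.idx(s.ix, s.iy, s.iz);
      int t = g.tissue[vcur];
      double scale = ref_density[t] > 0 ? g.density[vcur] / ref_density[t] : 0.0;
      double mu = (muc[t] + mupe[t]) * scale;
      double tnext = std::min(s.tmaxx, std::min(s.tmaxy, s.tmaxz));
      double seg = tnext - s.t;
      if (mu * seg >= tau - tacc && mu > 0) {
        double tint = s.t + (tau - tacc) / mu;
        p[0] += tint * d[0]; p[1] += tint * d[1]; p[2] += tint * d[2];
        interacted = true;
        break;
      }
      tacc += mu * seg;
      s.t = tnext;
      if (s.tmaxx <= s.tmaxy && s.tmaxx <= s.tmaxz) {
        s.ix += s.stepx; s.tmaxx += s.tdx;
      } else if (s.tmaxy <= s.tmaxz) {
        s.iy += s.stepy; s.tmaxy += s.tdy;
      } else {
        s.iz += s.stepz; s.tmaxz += s.tdz;
      }
    }
    if (!interacted) { eesc += E; return; }

    int t = g.tissue[vcur];
    double ppe = mupe[t] / (muc[t] + mupe[t]);
    if (unif_rand() < ppe) {
      deposit[vcur] += E;  // photoelectric: local deposit
      edep += E;
      return;
    }
    // Compton scatter
    double k = E / MEC2;
    double mu_sc = sample_kn_cosine(E);
    double Ep = E / (1.0 + k * (1.0 - mu_sc));
    double Ee = E - Ep;
    double phi = 2.0 * M_PI * unif_rand();
    // electron polar angle from momentum balance
    double theta = std::acos(std::min(1.0, std::max(-1.0, mu_sc)));
    double tan_half = std::tan(0.5 * theta);
    double de[3] = {d[0], d[1], d[2]};
    if (tan_half > 1e-12) {
      double cot_e = (1.0 + k) * tan_half;
      double theta_e = std::atan(1.0 / cot_e);
      deflect(de, std::cos(theta_e), phi + M_PI);
    }
    deflect(d, mu_sc, phi);
    if (Ee > 0) sink(p, de, Ee, vcur);
    E = Ep;
    if (E < o.cutoff) {
      deposit[vcur] += E;
      edep += E;
      return;
    }
  }
}

// ----------------------------------------------------------------------
// exported modular kernels

// [[Rcpp::export]]
List cpp_transport_xray(NumericMatrix pos, NumericMatrix dir, NumericVector energy,
                        IntegerVector tissue, NumericVector density,
                        IntegerVector dims, NumericVector spacing,
                        NumericVector origin,
                        NumericVector egrid, NumericMatrix mu_compton,
                        NumericMatrix mu_pe, NumericVector ref_density,
                        double cutoff) {
  Grid g = make_grid(tissue, density, dims, spacing, origin);
  int n = pos.nrow();
  int ne = egrid.size();
  NumericVector deposit(tissue.size());
  NumericVector edep(n), eesc(n);
  std::vector<double> epx, epy, epz, edx, edy, edz, een;
  std::vector<int> ehist;
  for (int i = 0; i < n; i++) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double dep = 0, esc = 0;
    run_xray(g, p, d, energy[i], egrid.begin(), ne,
             mu_compton.begin(), mu_pe.begin(), ref_density.begin(),
             XRayOpts{cutoff}, deposit.begin(), dep, esc,
             [&](const double *pp, const double *dd, double Ee, int) {
               epx.push_back(pp[0]); epy.push_back(pp[1]); epz.push_back(pp[2]);
               edx.push_back(dd[0]); edy.push_back(dd[1]); edz.push_back(dd[2]);
               een.push_back(Ee); ehist.push_back(i + 1);
             });
    edep[i] = dep; eesc[i] = esc;
  }
  int m = een.size();
  NumericMatrix e_pos(m, 3), e_dir(m, 3);
  NumericVector e_energy(m);
  IntegerVector e_history(m);
  for (int j = 0; j < m; j++) {
    e_pos(j, 0) = epx[j]; e_pos(j, 1) = epy[j]; e_pos(j, 2) = epz[j];
    e_dir(j, 0) = edx[j]; e_dir(j, 1) = edy[j]; e_dir(j, 2) = edz[j];
    e_energy[j] = een[j]; e_history[j] = ehist[j];
  }
  return List::create(_["deposit"] = deposit, _["e_pos"] = e_pos,
                      _["e_dir"] = e_dir, _["e_energy"] = e_energy,
                      _["e_history"] = e_history,
                      _["deposited"] = edep, _["escaped"] = eesc);
}

static List bank_to_list(const PhotonBank &b) {
  int m = b.lam.size();
  NumericMatrix bp(m, 3), bd(m, 3);
  NumericVector bl(m);
  IntegerVector bv(m);
  for (int j = 0; j < m; j++) {
    bp(j, 0) = b.px[j]; bp(j, 1) = b.py[j]; bp(j, 2) = b.pz[j];
    bd(j, 0) = b.dx[j]; bd(j, 1) = b.dy[j]; bd(j, 2) = b.dz[j];
    bl[j] = b.lam[j]; bv[j] = b.vox[j];
  }
  return List::create(_["pos"] = bp, _["dir"] = bd, _["wavelength"] = bl,
                      _["voxel"] = bv);
}

// [[Rcpp::export]]
List cpp_transport_electron(NumericMatrix pos, NumericMatrix dir,
                            NumericVector energy,
                            IntegerVector tissue, NumericVector density,
                            IntegerVector dims, NumericVector spacing,
                            NumericVector origin,
                            NumericVector egrid, NumericMatrix stopping,
                            NumericVector ref_density, NumericVector n_tissue,
                            double z_charge, double lambda1, double lambda2,
                            double step_mm, double e_cutoff,
                            int birth_filter, double keep_prob,
                            double bank_cap, bool analog) {
  Grid g = make_grid(tissue, density, dims, spacing, origin);
  int n = pos.nrow();
  int ne = egrid.size();
  NumericVector deposit(tissue.size()), emission(tissue.size());
  NumericVector edep(n), eesc(n);
  double n_emitted = 0.0;
  PhotonBank bank;
  EmitOpts o{z_charge, lambda1, lambda2, step_mm, e_cutoff,
             birth_filter, keep_prob, bank_cap, analog};
  for (int i = 0; i < n; i++) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double esc = run_electron(g, p, d, energy[i], egrid.begin(), ne,
                              stopping.begin(), ref_density.begin(),
                              n_tissue.begin(), o, deposit.begin(),
                              emission.begin(), n_emitted,
                              analog ? &bank : (PhotonBank *)nullptr);
    eesc[i] = esc;
    edep[i] = energy[i] - esc;
  }
  return List::create(_["deposit"] = deposit, _["emission"] = emission,
                      _["bank"] = bank_to_list(bank),
                      _["deposited"] = edep, _["escaped"] = eesc,
                      _["n_emitted"] = n_emitted);
}

// [[Rcpp::export]]
List cpp_simulate_beam(NumericMatrix pos, NumericMatrix dir, NumericVector energy,
                       IntegerVector tissue, NumericVector density,
                       IntegerVector dims, NumericVector spacing,
                       NumericVector origin,
                       NumericVector egrid, NumericMatrix mu_compton,
                       NumericMatrix mu_pe, NumericMatrix stopping,
                       NumericVector ref_density, NumericVector n_tissue,
                       double z_charge, double lambda1, double lambda2,
                       double step_mm, double e_cutoff, double x_cutoff,
                       int birth_filter, double keep_prob,
                       double bank_cap, bool analog) {
  Grid g = make_grid(tissue, density, dims, spacing, origin);
  int n = pos.nrow();
  int ne = egrid.size();
  NumericVector deposit(tissue.size()), emission(tissue.size());
  NumericVector edep(n), eesc(n);
  double n_emitted = 0.0;
  PhotonBank bank;
  EmitOpts o{z_charge, lambda1, lambda2, step_mm, e_cutoff,
             birth_filter, keep_prob, bank_cap, analog};
  for (int i = 0; i < n; i++) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double dep = 0, esc = 0;
    run_xray(g, p, d, energy[i], egrid.begin(), ne,
             mu_compton.begin(), mu_pe.begin(), ref_density.begin(),
             XRayOpts{x_cutoff}, deposit.begin(), dep, esc,
             [&](const double *pp, const double *dd, double Ee, int) {
               double ep[3] = {pp[0], pp[1], pp[2]};
               double ed[3] = {dd[0], dd[1], dd[2]};
               double e_esc = run_electron(g, ep, ed, Ee, egrid.begin(), ne,
                                           stopping.begin(),
                                           ref_density.begin(),
                                           n_tissue.begin(), o,
                                           deposit.begin(), emission.begin(),
                                           n_emitted,
                                           analog ? &bank
                                                  : (PhotonBank *)nullptr);
               dep += Ee - e_esc;
               esc += e_esc;
             });
    edep[i] = dep; eesc[i] = esc;
    if (i % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["deposit"] = deposit, _["emission"] = emission,
                      _["bank"] = bank_to_list(bank),
                      _["deposited"] = edep, _["escaped"] = eesc,
                      _["n_emitted"] = n_emitted);
}

// ----------------------------------------------------------------------
// optical photon tracing

static inline double fresnel_R(double cos_i, double n1, double n2,
                               double &cos_t) {
  double s2 = (n1 / n2) * (n1 / n2) * (1.0 - cos_i * cos_i);
  if (s2 >= 1.0) { cos_t = 0.0; return 1.0; }  // total internal reflection
  cos_t = std::sqrt(1.0 - s2);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein inverse-CDF sample of the deflection cosine
static inline double sample_hg(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - f * f) / (2.0 * g);
}

// face codes 1..6: +x, -x, +y, -y, +z, -z
static inline int face_code(int axis, int step) {
  return axis * 2 + (step > 0 ? 1 : 2);
}

// [[Rcpp::export]]
List cpp_trace_optical(NumericMatrix pos, NumericMatrix dir,
                       NumericVector wavelength,
                       IntegerVector tissue, NumericVector density,
                       IntegerVector dims, NumericVector spacing,
                       NumericVector origin,
                       NumericVector lgrid, NumericMatrix mu_a,
                       NumericMatrix mu_s, NumericMatrix g_mat,
                       NumericVector n_tissue,
                       bool fresnel, double event_cap, bool score_fluence) {
  Grid g = make_grid(tissue, density, dims, spacing, origin);
  int n = pos.nrow();
  int nl = lgrid.size();
  int nT = n_tissue.size();
  IntegerVector status(n);            // 0 absorbed, 1 exited, 2 capped
  IntegerVector abs_voxel(n, NA_INTEGER);
  IntegerVector exit_voxel(n, NA_INTEGER);
  IntegerVector exit_face(n, NA_INTEGER);
  NumericMatrix exit_pos(n, 3), exit_dir(n, 3);
  NumericVector n_events(n);
  NumericVector fluence(score_fluence ? tissue.size() : 1);
  const double sp[3] = {g.sx, g.sy, g.sz};
  double eps = 1e-9 * (g.sx + g.sy + g.sz);

  std::vector<double> mua_t(nT), mus_t(nT), g_t(nT);

  for (int i = 0; i < n; i++) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double lam = wavelength[i];
    for (int t = 0; t < nT; t++) {
      mua_t[t] = interp1(lgrid.begin(), mu_a.begin() + (size_t)nl * t, nl, lam);
      mus_t[t] = interp1(lgrid.begin(), mu_s.begin() + (size_t)nl * t, nl, lam);
      g_t[t] = interp1(lgrid.begin(), g_mat.begin() + (size_t)nl * t, nl, lam);
    }
    int ix, iy, iz;
    if (!g.voxel_of(p, ix, iy, iz) || g.tissue[g.idx(ix, iy, iz)] == 0) {
      Rcpp::stop("optical photon starting in air or outside the grid");
    }
    long events = 0;
    int st = -1;
    while (st < 0) {
      double tau = -std::log(unif_rand());
      bool flight_done = false;
      while (!flight_done) {
        DDA s;
        dda_init(g, p, d, s);
        double fp[3] = {p[0], p[1], p[2]};
        bool restart = false;
        while (!restart) {
          int vcur = g.idx(s.ix, s.iy, s.iz);
          int t = g.tissue[vcur];
          double mu = mua_t[t] + mus_t[t];
          double tnext = std::min(s.tmaxx, std::min(s.tmaxy, s.tmaxz));
          double seg = tnext - s.t;
          if (mu * seg >= tau && mu > 0) {
            // interaction inside this voxel
            double tint = s.t + tau / mu;
            if (score_fluence) fluence[vcur] += tau / mu;
            p[0] = fp[0] + tint * d[0];
            p[1] = fp[1] + tint * d[1];
            p[2] = fp[2] + tint * d[2];
            events++;
            if (unif_rand() < mua_t[t] / mu) {
              st = 0; abs_voxel[i] = vcur + 1;          // absorbed (1-based)
            } else if (events >= (long)event_cap) {
              st = 2; abs_voxel[i] = vcur + 1;          // cap: treated as absorbed
            } else {
              deflect(d, sample_hg(g_t[t]), 2.0 * M_PI * unif_rand());
            }
            flight_done = true;
            restart = true;
            continue;
          }
          if (score_fluence) fluence[vcur] += seg;
          tau -= mu * seg;
          s.t = tnext;
          int axis;
          if (s.tmaxx <= s.tmaxy && s.tmaxx <= s.tmaxz) axis = 0;
          else if (s.tmaxy <= s.tmaxz) axis = 1;
          else axis = 2;
          int stepa = (axis == 0) ? s.stepx : (axis == 1) ? s.stepy : s.stepz;
          int jx = s.ix + (axis == 0 ? stepa : 0);
          int jy = s.iy + (axis == 1 ? stepa : 0);
          int jz = s.iz + (axis == 2 ? stepa : 0);
          bool next_in = g.inside(jx, jy, jz);
          bool next_air = next_in && g.tissue[g.idx(jx, jy, jz)] == 0;
          if (next_in && !next_air) {
            // interior tissue-tissue crossing: index-matched, keep marching
            s.ix = jx; s.iy = jy; s.iz = jz;
            if (axis == 0) s.tmaxx += s.tdx;
            else if (axis == 1) s.tmaxy += s.tdy;
            else s.tmaxz += s.tdz;
            continue;
          }
          // tissue-air (or domain) boundary at distance tnext
          double hit[3] = {fp[0] + tnext * d[0], fp[1] + tnext * d[1],
                           fp[2] + tnext * d[2]};
          double cos_i = std::fabs(d[axis]);
          double n1 = n_tissue[t], n2 = 1.0;
          double cos_t, R;
          if (fresnel) R = fresnel_R(cos_i, n1, n2, cos_t);
          else { R = 0.0; cos_t = cos_i; }
          events++;
          if (events >= (long)event_cap && R > 0) {
            st = 2; abs_voxel[i] = vcur + 1;
            flight_done = true; restart = true;
            continue;
          }
          if (unif_rand() < R) {
            // reflect: flip the normal component, restart flight
            d[axis] = -d[axis];
            p[0] = hit[0]; p[1] = hit[1]; p[2] = hit[2];
            p[axis] -= stepa * eps;
            restart = true;
            continue;
          }
          // transmit: refract (or pass unchanged when Fresnel is off)
          double nvec[3] = {0, 0, 0};
          nvec[axis] = (double)stepa;
          if (fresnel) {
            double eta = n1 / n2;
            for (int a = 0; a < 3; a++) {
              d[a] = eta * d[a] - (eta * cos_i - cos_t) * nvec[a];
            }
            double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
            d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
          }
          st = 1;
          exit_voxel[i] = vcur + 1;
          exit_face[i] = face_code(axis, stepa);
          exit_pos(i, 0) = hit[0]; exit_pos(i, 1) = hit[1];
          exit_pos(i, 2) = hit[2];
          exit_dir(i, 0) = d[0]; exit_dir(i, 1) = d[1]; exit_dir(i, 2) = d[2];
          flight_done = true;
          restart = true;
        }
      }
    }
    status[i] = st;
    n_events[i] = (double)events;
    if (i % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  (void)sp;
  List out = List::create(_["status"] = status, _["abs_voxel"] = abs_voxel,
                          _["exit_voxel"] = exit_voxel,
                          _["exit_face"] = exit_face,
                          _["exit_pos"] = exit_pos, _["exit_dir"] = exit_dir,
                          _["n_events"] = n_events);
  if (score_fluence) out["fluence"] = fluence;
  return out;
}
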