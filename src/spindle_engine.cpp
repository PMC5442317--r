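// Core Brownian dynamics / kinetic Monte Carlo engine for motor-free spindle
// assembly: mobile SPBs in a spherical nuclear envelope, rigid dynamic MTs
// tethered to SPB nucleation sites, and antiparallel crosslinkers whose
// binding kinetics follow the filament-pair partition function.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include "spindle_vec.h"
#include "spindle_rng.h"
#include "spindle_model.h"

using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;
using Rcpp::IntegerMatrix;

namespace {

const double GOLDEN_ANGLE = 2.399963229728653;
const double K_SPB_STERIC = 50.0;  // pN/um, SPB-SPB disk overlap repulsion

struct MT {
  Vec3 c, n;     // center, unit orientation (minus -> plus)
  double L;
  int state;     // +1 growing, -1 shrinking
  int spb, site;
  // per-step scratch
  Vec3 F, T;
  double f_ax;   // compressive axial load on the plus tip (wall)
  bool stab;
  // cached slender-body drag, refreshed when the length drifts
  double gL = -1, g_par = 0, g_perp = 0, g_rot = 0;
  Vec3 minus() const { return c - n * (0.5 * L); }
  Vec3 plus() const { return c + n * (0.5 * L); }
};

struct SPB {
  Vec3 u, e1, e2;  // radial unit vector and in-plane frame
  Vec3 F;
  double T_u;
};

struct XL {
  int state;          // 0 free, 1 one head bound, 2 crosslinking
  Vec3 pos;           // free position
  int mt[2];
  double x[2];        // arc coordinate from the minus end
};

struct ForceDecomp {
  std::vector<Vec3> tether, steric, xlink, wall;       // per MT
  std::vector<Vec3> t_tether, t_steric, t_xlink, t_wall;
  Vec3 spb_tether[2], spb_steric[2];
  double spb_torque[2];
};

class Engine {
 public:
  Params P;
  Rng rng;
  std::vector<MT> mts;
  SPB spb[2];
  std::vector<XL> xls;
  // all rod pairs with a lazy distance-bound: a pair's minimum distance is
  // recomputed only after accumulated motion could have closed its slack
  std::vector<std::pair<int, int> > pairs;
  std::vector<double> pr_slack, pr_alast;
  double A_total = 0.0;
  std::vector<std::pair<double, double> > site_xy;
  double t = 0.0;
  long step_idx = 0;
  long cap_events = 0;
  // scratch for pair-binding candidate bookkeeping
  std::vector<int> cand_mt;
  std::vector<double> cand_w, cand_lo, cand_hi;

  Engine(const Params& p, uint64_t seed) : P(p), rng(seed) {
    site_xy.resize(P.sites_per_spb);
    for (int k = 0; k < P.sites_per_spb; ++k) {
      double rr = P.r_spb * std::sqrt((k + 0.5) / P.sites_per_spb);
      double ang = k * GOLDEN_ANGLE;
      site_xy[k] = std::make_pair(rr * std::cos(ang), rr * std::sin(ang));
    }
  }

  Vec3 anchor(int s, int k) const {
    Vec3 w = spb[s].u * P.R + spb[s].e1 * site_xy[k].first +
             spb[s].e2 * site_xy[k].second;
    return normalize(w) * P.R;
  }

  // preferred orientation of a nucleation site: inward disk normal tilted
  // outward on a cone by the site's radial position on the disk
  Vec3 site_normal(int s, int k) const {
    Vec3 inward = -spb[s].u;
    Vec3 tilt = spb[s].e1 * site_xy[k].first + spb[s].e2 * site_xy[k].second;
    return normalize(inward + tilt * (P.cone / P.r_spb));
  }

  void init() {
    double sa = P.r_spb / P.R;
    if (sa >= 1.0) Rcpp::stop("SPB diameter exceeds what the envelope allows");
    double a = P.init_angle > 0 ? 0.5 * P.init_angle : std::asin(sa);
    spb[0].u = Vec3(std::sin(a), 0, std::cos(a));
    spb[1].u = Vec3(-std::sin(a), 0, std::cos(a));
    for (int s = 0; s < 2; ++s) {
      perp_basis(spb[s].u, spb[s].e1, spb[s].e2);
      spb[s].F = Vec3();
      spb[s].T_u = 0;
    }
    mts.clear();
    for (int s = 0; s < 2; ++s) {
      for (int k = 0; k < P.sites_per_spb; ++k) {
        MT m;
        m.spb = s;
        m.site = k;
        Vec3 A = anchor(s, k);
        Vec3 n0 = site_normal(s, k);
        Vec3 p1, p2;
        perp_basis(n0, p1, p2);
        m.n = normalize(n0 + p1 * (0.05 * rng.rnorm()) +
                        p2 * (0.05 * rng.rnorm()));
        m.L = P.L_init;
        m.c = A + m.n * (0.5 * m.L);
        m.state = 1;
        m.f_ax = 0;
        m.stab = false;
        mts.push_back(m);
      }
    }
    xls.clear();
    xls.resize(P.n_xl);
    for (int i = 0; i < P.n_xl; ++i) {
      XL& x = xls[i];
      x.state = 0;
      do {
        x.pos = Vec3(P.R * (2 * rng.runif() - 1), P.R * (2 * rng.runif() - 1),
                     P.R * (2 * rng.runif() - 1));
      } while (norm2(x.pos) > P.R * P.R);
      x.mt[0] = x.mt[1] = -1;
      x.x[0] = x.x[1] = 0;
    }
    t = 0;
    step_idx = 0;
    build_pairs();
  }

  void build_pairs() {
    pairs.clear();
    const int n = (int)mts.size();
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        pairs.push_back(std::make_pair(i, j));
    pr_slack.assign(pairs.size(), -1.0);
    pr_alast.assign(pairs.size(), 0.0);
    A_total = 0.0;
  }

  void compute_forces(ForceDecomp* dec) {
    const int n = (int)mts.size();
    if (dec) {
      dec->tether.assign(n, Vec3());  dec->steric.assign(n, Vec3());
      dec->xlink.assign(n, Vec3());   dec->wall.assign(n, Vec3());
      dec->t_tether.assign(n, Vec3()); dec->t_steric.assign(n, Vec3());
      dec->t_xlink.assign(n, Vec3()); dec->t_wall.assign(n, Vec3());
      for (int s = 0; s < 2; ++s) {
        dec->spb_tether[s] = Vec3(); dec->spb_steric[s] = Vec3();
        dec->spb_torque[s] = 0;
      }
    }
    for (int i = 0; i < n; ++i) {
      mts[i].F = Vec3();
      mts[i].T = Vec3();
      mts[i].f_ax = 0;
    }
    for (int s = 0; s < 2; ++s) { spb[s].F = Vec3(); spb[s].T_u = 0; }

    // minus-end tethers
    for (int i = 0; i < n; ++i) {
      MT& m = mts[i];
      Vec3 A = anchor(m.spb, m.site);
      Vec3 mn = m.minus();
      Vec3 d = mn - A;
      double dist = norm(d);
      Vec3 f;
      if (dist > 1e-12) {
        double mag = -P.k_tether * (dist - P.tether_rest);
        f = d * (mag / dist);
      }
      m.F += f;
      m.T += cross(mn - m.c, f);
      spb[m.spb].F -= f;
      spb[m.spb].T_u += dot(cross(A - spb[m.spb].u * P.R, -f), spb[m.spb].u);
      // angular restraint toward the nucleation-site normal: the site is a
      // hinge with orientation stiffness, not a free pivot
      Vec3 Tang;
      if (P.k_ang > 0) {
        Vec3 n0 = site_normal(m.spb, m.site);
        Tang = cross(m.n, n0) * P.k_ang;
        m.T += Tang;
        spb[m.spb].T_u -= dot(Tang, spb[m.spb].u);
      }
      if (dec) {
        dec->tether[i] += f;
        dec->t_tether[i] += cross(mn - m.c, f) + Tang;
        dec->spb_tether[m.spb] -= f;
        dec->spb_torque[m.spb] +=
            dot(cross(A - spb[m.spb].u * P.R, -f), spb[m.spb].u) -
            dot(Tang, spb[m.spb].u);
      }
    }

    // WCA sterics between rods
    const double sig = P.d_mt;
    const double rc = std::pow(2.0, 1.0 / 6.0) * sig;
    const double eps = P.steric_eps_kt * P.kT;
    for (size_t q = 0; q < pairs.size(); ++q) {
      if (pr_slack[q] > 0 &&
          2.0 * (A_total - pr_alast[q]) < pr_slack[q])
        continue;  // pair cannot have reached contact yet
      int i = pairs[q].first, j = pairs[q].second;
      MT &a = mts[i], &b = mts[j];
      Vec3 a0 = a.minus(), da = a.n * a.L;
      Vec3 b0 = b.minus(), db = b.n * b.L;
      double s, u;
      double d2 = segment_segment_dist2(a0, da, b0, db, s, u);
      pr_alast[q] = A_total;
      if (d2 >= rc * rc) {
        pr_slack[q] = std::sqrt(d2) - rc;
        continue;
      }
      pr_slack[q] = 0.0;
      Vec3 pa = a0 + da * s, pb = b0 + db * u;
      Vec3 dv = pa - pb;
      double r = std::sqrt(d2);
      if (r < 1e-8) {
        // coincident rods: deterministic tie-break along a fixed axis
        dv = Vec3(1e-6, 0, 0);
        pa += dv;
        r = 1e-6;
      }
      double rr = r < 0.6 * sig ? 0.6 * sig : r;  // force cap
      double sr6 = std::pow(sig / rr, 6.0);
      double fmag = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / rr;
      Vec3 f = dv * (fmag / r);
      a.F += f;
      a.T += cross(pa - a.c, f);
      b.F -= f;
      b.T += cross(pb - b.c, -f);
      if (dec) {
        dec->steric[i] += f;  dec->t_steric[i] += cross(pa - a.c, f);
        dec->steric[j] -= f;  dec->t_steric[j] += cross(pb - b.c, -f);
      }
    }

    // SPB-SPB disk repulsion
    {
      Vec3 d = spb[0].u * P.R - spb[1].u * P.R;
      double dist = norm(d);
      double contact = 2.0 * P.r_spb;
      if (dist < contact && dist > 1e-12) {
        Vec3 f = d * (K_SPB_STERIC * (contact - dist) / dist);
        spb[0].F += f;
        spb[1].F -= f;
        if (dec) { dec->spb_steric[0] += f; dec->spb_steric[1] -= f; }
      }
    }

    // polymerization pushing on the opposite pole: MTs repel the other
    // SPB's disk (approximated as a sphere of the disk radius)
    {
      const double contact = P.r_spb + 0.5 * P.d_mt;
      const double K_PUSH = 200.0;  // pN/um, capped below
      for (int i = 0; i < n; ++i) {
        MT& m = mts[i];
        int so = 1 - m.spb;
        Vec3 C = spb[so].u * P.R;
        Vec3 mn = m.minus();
        double tt0 = dot(C - mn, m.n);
        if (tt0 < 0) tt0 = 0; else if (tt0 > m.L) tt0 = m.L;
        Vec3 pcl = mn + m.n * tt0;
        Vec3 d = pcl - C;
        double dist = norm(d);
        if (dist >= contact || dist < 1e-9) continue;
        double fmag = K_PUSH * (contact - dist);
        if (fmag > 20.0) fmag = 20.0;
        Vec3 f = d * (fmag / dist);
        m.F += f;
        m.T += cross(pcl - m.c, f);
        spb[so].F -= f;
        // pole contact loads the plus tip: polymerization pushes the
        // opposite SPB and growth stalls per the ratchet law
        double ax = -dot(f, m.n);
        if (ax > 0 && tt0 > 0.9 * m.L) m.f_ax += ax;
        if (dec) {
          dec->steric[i] += f;
          dec->t_steric[i] += cross(pcl - m.c, f);
          dec->spb_steric[so] -= f;
        }
      }
    }

    // crosslink springs (doubly bound)
    for (size_t q = 0; q < xls.size(); ++q) {
      XL& x = xls[q];
      if (x.state != 2) continue;
      MT &a = mts[x.mt[0]], &b = mts[x.mt[1]];
      Vec3 pa = a.minus() + a.n * x.x[0];
      Vec3 pb = b.minus() + b.n * x.x[1];
      Vec3 d = pb - pa;
      double dist = norm(d);
      if (dist < 1e-12) continue;
      double mag = P.k_xl * (dist - P.r0_xl);  // >0 stretched: attract
      Vec3 f = d * (mag / dist);               // force on a toward b
      a.F += f;
      a.T += cross(pa - a.c, f);
      b.F -= f;
      b.T += cross(pb - b.c, -f);
      if (dec) {
        dec->xlink[x.mt[0]] += f;
        dec->t_xlink[x.mt[0]] += cross(pa - a.c, f);
        dec->xlink[x.mt[1]] -= f;
        dec->t_xlink[x.mt[1]] += cross(pb - b.c, -f);
      }
    }

    // NE wall force on protruding plus tips, radially inward
    if (P.F_w > 0) {
      for (int i = 0; i < n; ++i) {
        MT& m = mts[i];
        Vec3 p = m.plus();
        double r = norm(p);
        double L = r - P.R;
        if (L <= 0) continue;
        double fmag = wall_force_value(L, P.F_w, P.R_tube, P.euler_gamma,
                                       P.const_a, P.const_c, P.blend_len,
                                       0.5 * P.d_mt);
        Vec3 dir = p * (-1.0 / r);
        Vec3 f = dir * fmag;
        m.F += f;
        m.T += cross(p - m.c, f);
        double ax = fmag * dot(m.n, p) / r;  // compressive component
        if (ax > 0) m.f_ax += ax;
        if (dec) { dec->wall[i] += f; dec->t_wall[i] += cross(p - m.c, f); }
      }
    }
  }

  // crosslink-induced stabilization: flag MTs with a crosslink head within
  // arc distance s of the plus end
  void update_stabilization() {
    for (size_t i = 0; i < mts.size(); ++i) mts[i].stab = false;
    if (!P.stab_enabled) return;
    for (size_t q = 0; q < xls.size(); ++q) {
      XL& x = xls[q];
      if (x.state != 2) continue;
      for (int h = 0; h < 2; ++h) {
        MT& m = mts[x.mt[h]];
        if (m.L - x.x[h] <= P.s_len) m.stab = true;
      }
    }
  }

  void di_and_growth_step() {
    double max_dL = 0.0;
    for (size_t i = 0; i < mts.size(); ++i) {
      MT& m = mts[i];
      double fc = m.stab ? P.f_c / P.s_fc : P.f_c;
      double fr = m.stab ? P.f_r * P.s_fr : P.f_r;
      double vg = m.stab ? P.v_g * P.s_vg : P.v_g;
      double vs = m.stab ? P.v_s / P.s_vs : P.v_s;
      double v = ratchet_speed(m.f_ax, vg, P.F_s, P.sigma, P.kT);
      if (P.force_catastrophe && m.f_ax > 0) {
        // loaded plus ends catastrophe more often, in inverse proportion to
        // the ratchet growth speed (capped)
        double boost = v > vg / P.force_catastrophe_cap
                           ? vg / v
                           : P.force_catastrophe_cap;
        fc *= boost;
      }
      double u = rng.runif();
      if (m.state == 1) {
        if (u < -std::expm1(-fc * P.dt)) m.state = -1;
      } else {
        if (u < -std::expm1(-fr * P.dt)) m.state = 1;
      }
      Vec3 mn = m.minus();
      double L_old = m.L;
      if (m.state == 1) {
        m.L += v * P.dt;
      } else {
        m.L -= vs * P.dt;
        if (m.L < P.L_min) {
          m.L = P.L_min;
          m.state = 1;  // renucleation from the SPB
        }
      }
      double dL = std::fabs(m.L - L_old);
      if (dL > max_dL) max_dL = dL;
      m.c = mn + m.n * (0.5 * m.L);
    }
    A_total += max_dL;
    // heads stranded past a shrinking plus end fall off
    for (size_t q = 0; q < xls.size(); ++q) {
      XL& x = xls[q];
      if (x.state == 2) {
        bool off0 = x.x[0] > mts[x.mt[0]].L;
        bool off1 = x.x[1] > mts[x.mt[1]].L;
        if (off0 && off1) {
          free_at(x, mts[x.mt[0]].plus());
        } else if (off0) {
          x.mt[0] = x.mt[1]; x.x[0] = x.x[1];
          x.state = 1; x.mt[1] = -1;
        } else if (off1) {
          x.state = 1; x.mt[1] = -1;
        }
      } else if (x.state == 1 && x.x[0] > mts[x.mt[0]].L) {
        free_at(x, mts[x.mt[0]].plus());
      }
    }
  }

  void free_at(XL& x, Vec3 where) {
    x.state = 0;
    double r = norm(where);
    x.pos = (r > P.R) ? where * (P.R / r * 0.999) : where;
    x.mt[0] = x.mt[1] = -1;
  }

  // partition weight of candidate MT j for a head anchored at point h;
  // midpoint-rule integral of exp(-E/kT) over the reachable arc window
  double pair_weight(const Vec3& h, int j, double& lo, double& hi) {
    const MT& m = mts[j];
    Vec3 mn = m.minus();
    Vec3 w = h - mn;
    double tpar = dot(w, m.n);
    double dperp2 = norm2(w) - tpar * tpar;
    if (dperp2 < 0) dperp2 = 0;
    double reach = P.r0_xl + std::sqrt(2.0 * P.e_cut_kt * P.kT / P.k_xl);
    double reach2 = reach * reach;
    if (dperp2 >= reach2) return 0.0;
    double shalf = std::sqrt(reach2 - dperp2);
    lo = tpar - shalf;
    hi = tpar + shalf;
    if (lo < P.minus_excl) lo = P.minus_excl;  // SPB plaque occludes the lattice
    if (hi > m.L) hi = m.L;
    if (hi <= lo) return 0.0;
    double width = hi - lo;
    int nb = (int)std::ceil(width / P.quad_bin);
    if (nb < 8) nb = 8;
    double hbin = width / nb;
    double sum = 0.0;
    for (int b = 0; b < nb; ++b) {
      double s = lo + (b + 0.5) * hbin;
      double ds2 = dperp2 + (s - tpar) * (s - tpar);
      double d = std::sqrt(ds2);
      double e = 0.5 * P.k_xl * (d - P.r0_xl) * (d - P.r0_xl);
      sum += std::exp(-e / P.kT);
    }
    return P.k2_on * sum * hbin;
  }

  // draw a landing arc coordinate from the Boltzmann density on [lo, hi]
  double sample_landing(const Vec3& h, int j, double lo, double hi) {
    const MT& m = mts[j];
    Vec3 mn = m.minus();
    Vec3 w = h - mn;
    double tpar = dot(w, m.n);
    double dperp2 = norm2(w) - tpar * tpar;
    if (dperp2 < 0) dperp2 = 0;
    double width = hi - lo;
    int nb = (int)std::ceil(width / P.quad_bin);
    if (nb < 8) nb = 8;
    double hbin = width / nb;
    std::vector<double> wts(nb);
    double tot = 0;
    for (int b = 0; b < nb; ++b) {
      double s = lo + (b + 0.5) * hbin;
      double d = std::sqrt(dperp2 + (s - tpar) * (s - tpar));
      double e = 0.5 * P.k_xl * (d - P.r0_xl) * (d - P.r0_xl);
      wts[b] = std::exp(-e / P.kT);
      tot += wts[b];
    }
    double u = rng.runif() * tot;
    int b = 0;
    for (; b < nb - 1; ++b) {
      if (u < wts[b]) break;
      u -= wts[b];
    }
    return lo + (b + rng.runif()) * hbin;
  }

  bool antiparallel(int i, int j) const {
    return dot(mts[i].n, mts[j].n) < P.ap_threshold;
  }

  void xl_kmc_step() {
    const bool pair_turn = (step_idx % P.xl_pair_interval) == 0;
    const bool free_turn = (step_idx % P.xl_free_interval) == 0;
    const double dt_pair = P.dt * P.xl_pair_interval;
    const double dt_free = P.dt * P.xl_free_interval;
    const int n = (int)mts.size();

    for (size_t q = 0; q < xls.size(); ++q) {
      XL& x = xls[q];
      if (x.state == 2) {
        // unbinding of either head; optional Bell force dependence
        double bell = 1.0;
        if (P.bell_x > 0) {
          Vec3 pa = mts[x.mt[0]].minus() + mts[x.mt[0]].n * x.x[0];
          Vec3 pb = mts[x.mt[1]].minus() + mts[x.mt[1]].n * x.x[1];
          double fs = P.k_xl * std::fabs(norm(pb - pa) - P.r0_xl);
          bell = std::exp(fs * P.bell_x / P.kT);
        }
        double tot = 2.0 * P.k2_off * bell;
        if (rng.runif() < -std::expm1(-tot * P.dt)) {
          int h = rng.runif() < 0.5 ? 0 : 1;  // equal rates per head
          if (h == 0) { x.mt[0] = x.mt[1]; x.x[0] = x.x[1]; }
          x.state = 1;
          x.mt[1] = -1;
        }
      } else if (x.state == 1 && pair_turn) {
        // unbind, or bind the second head to an antiparallel partner with
        // probability set by the pair partition weight
        const MT& m0 = mts[x.mt[0]];
        Vec3 h = m0.minus() + m0.n * x.x[0];
        cand_mt.clear(); cand_w.clear(); cand_lo.clear(); cand_hi.clear();
        double wsum = 0;
        for (int j = 0; j < n; ++j) {
          if (j == x.mt[0] || !antiparallel(x.mt[0], j)) continue;
          // cheap reach prefilter on the candidate's bounding sphere
          double rmax = 0.5 * mts[j].L + P.r0_xl +
                        std::sqrt(2.0 * P.e_cut_kt * P.kT / P.k_xl);
          if (norm2(h - mts[j].c) > rmax * rmax) continue;
          double lo, hi;
          double w = pair_weight(h, j, lo, hi);
          if (w > 0) {
            cand_mt.push_back(j); cand_w.push_back(w);
            cand_lo.push_back(lo); cand_hi.push_back(hi);
            wsum += w;
          }
        }
        double tot = P.k1_off + wsum;
        if (rng.runif() < -std::expm1(-tot * dt_pair)) {
          double u = rng.runif() * tot;
          if (u < P.k1_off) {
            free_at(x, h);
          } else {
            u -= P.k1_off;
            size_t c = 0;
            for (; c + 1 < cand_w.size(); ++c) {
              if (u < cand_w[c]) break;
              u -= cand_w[c];
            }
            x.mt[1] = cand_mt[c];
            x.x[1] = sample_landing(h, cand_mt[c], cand_lo[c], cand_hi[c]);
            x.state = 2;
          }
        }
      } else if (x.state == 0 && free_turn) {
        // bind a first head: rate proportional to MT arc length within the
        // capture radius of the crosslinker position
        double rc2 = P.capture_radius * P.capture_radius;
        double lsum = 0;
        double seg_lo[64], seg_len[64];
        int seg_mt[64];
        int nseg = 0;
        for (int j = 0; j < n && nseg < 64; ++j) {
          const MT& m = mts[j];
          double rmax = 0.5 * m.L + P.capture_radius;
          if (norm2(x.pos - m.c) > rmax * rmax) continue;
          Vec3 w = x.pos - m.minus();
          double tpar = dot(w, m.n);
          double dperp2 = norm2(w) - tpar * tpar;
          if (dperp2 >= rc2) continue;
          double half = std::sqrt(rc2 - dperp2);
          double lo = tpar - half, hi = tpar + half;
          if (lo < P.minus_excl) lo = P.minus_excl;
          if (hi > m.L) hi = m.L;
          if (hi <= lo) continue;
          seg_mt[nseg] = j; seg_lo[nseg] = lo; seg_len[nseg] = hi - lo;
          lsum += hi - lo;
          ++nseg;
        }
        if (lsum > 0 &&
            rng.runif() < -std::expm1(-P.k1_on * lsum * dt_free)) {
          double u = rng.runif() * lsum;
          int c = 0;
          for (; c + 1 < nseg; ++c) {
            if (u < seg_len[c]) break;
            u -= seg_len[c];
          }
          x.state = 1;
          x.mt[0] = seg_mt[c];
          x.x[0] = seg_lo[c] + rng.runif() * seg_len[c];
        }
      }
    }
  }

  void xl_diffusion_step() {
    const bool free_turn = (step_idx % P.xl_free_interval) == 0;
    const bool pair_turn = (step_idx % P.xl_pair_interval) == 0;
    const double dt_free = P.dt * P.xl_free_interval;
    const double sd_bound = std::sqrt(2.0 * P.D_bound * P.dt);
    const double sd_tracer =
        std::sqrt(2.0 * P.D_bound * P.dt * P.xl_pair_interval);
    const double sd_free = std::sqrt(2.0 * P.D_free * dt_free);
    const double mob = P.D_bound / P.kT;

    for (size_t q = 0; q < xls.size(); ++q) {
      XL& x = xls[q];
      if (x.state == 1) {
        if (!pair_turn) continue;  // tracer heads only matter on pair turns
        double L = mts[x.mt[0]].L;
        double xx = x.x[0] + sd_tracer * rng.rnorm();
        if (xx > L || xx < 0) {
          if (P.end_release) {
            // the lattice ends: a head stepping past either end falls off
            free_at(x, xx > L ? mts[x.mt[0]].plus() : mts[x.mt[0]].minus());
            continue;
          }
          xx = xx > L ? L : 0;  // clamp at the lattice ends
        }
        x.x[0] = xx;
      } else if (x.state == 2) {
        for (int h = 0; h < 2; ++h) {
          const MT& m = mts[x.mt[h]];
          const MT& o = mts[x.mt[1 - h]];
          Vec3 p = m.minus() + m.n * x.x[h];
          Vec3 qo = o.minus() + o.n * x.x[1 - h];
          Vec3 d = qo - p;
          double dist = norm(d);
          if (dist < 1e-9) dist = 1e-9;
          double npar = dot(m.n, d);
          double fx = P.k_xl * (dist - P.r0_xl) * npar / dist;
          double dperp2 = dist * dist - npar * npar;
          if (dperp2 < 0) dperp2 = 0;
          double keff = P.k_xl * (npar / dist) * (npar / dist) +
                        P.k_xl * (1.0 - P.r0_xl / dist) * dperp2 /
                            (dist * dist);
          double xx;
          if (keff * mob * P.dt < 0.01) {
            xx = x.x[h] + mob * fx * P.dt + sd_bound * rng.rnorm();
          } else {
            // locally linearized Ornstein-Uhlenbeck update: stable for
            // stiff springs at any timestep
            double xstar = x.x[h] + fx / keff;
            double a = std::exp(-mob * keff * P.dt);
            xx = xstar + (x.x[h] - xstar) * a +
                 std::sqrt(P.kT / keff * (1.0 - a * a)) * rng.rnorm();
          }
          if (xx > m.L || xx < 0) {
            if (P.end_release) {
              // dragged or diffused past a lattice end: this head falls off
              if (h == 0) { x.mt[0] = x.mt[1]; x.x[0] = x.x[1]; }
              x.state = 1;
              x.mt[1] = -1;
              break;
            }
            xx = xx > m.L ? m.L : 0;  // clamp at the lattice ends
          }
          x.x[h] = xx;
        }
      } else if (free_turn) {
        x.pos += Vec3(sd_free * rng.rnorm(), sd_free * rng.rnorm(),
                      sd_free * rng.rnorm());
        double r = norm(x.pos);
        if (r > P.R) {
          double rnew = 2.0 * P.R - r;
          if (rnew < 0.1 * P.R) rnew = 0.1 * P.R;
          x.pos = x.pos * (rnew / r);
        }
      }
    }
  }

  void brownian_move() {
    // rods
    double max_disp = 0.0;
    for (size_t i = 0; i < mts.size(); ++i) {
      MT& m = mts[i];
      if (m.gL < 0 || std::fabs(m.L - m.gL) > 0.02 * m.gL) {
        rod_drag(m.L, P.d_mt, P.eta, m.g_par, m.g_perp, m.g_rot);
        m.gL = m.L;
      }
      double g_par = m.g_par, g_perp = m.g_perp, g_rot = m.g_rot;
      Vec3 c_old = m.c, n_old = m.n;
      Vec3 p1, p2;
      perp_basis(m.n, p1, p2);
      double f_par = dot(m.F, m.n);
      Vec3 F_perp = m.F - m.n * f_par;
      Vec3 drift = (m.n * (f_par / g_par) + F_perp * (1.0 / g_perp)) * P.dt;
      double dn = norm(drift);
      if (dn > P.cap_trans) {
        drift = drift * (P.cap_trans / dn);
        ++cap_events;
      }
      double sd_par = std::sqrt(2.0 * P.kT * P.dt / g_par);
      double sd_perp = std::sqrt(2.0 * P.kT * P.dt / g_perp);
      m.c += drift + m.n * (sd_par * rng.rnorm()) +
             p1 * (sd_perp * rng.rnorm()) + p2 * (sd_perp * rng.rnorm());
      // rotation about the center
      Vec3 T_perp = m.T - m.n * dot(m.T, m.n);
      Vec3 omega = T_perp * (1.0 / g_rot);
      Vec3 dn_det = cross(omega, m.n) * P.dt;
      double an = norm(dn_det);
      if (an > P.cap_rot) {
        dn_det = dn_det * (P.cap_rot / an);
        ++cap_events;
      }
      double sd_rot = std::sqrt(2.0 * P.kT * P.dt / g_rot);
      m.n = normalize(m.n + dn_det + p1 * (sd_rot * rng.rnorm()) +
                      p2 * (sd_rot * rng.rnorm()));
      double disp = norm(m.c - c_old) + 0.5 * m.L * norm(m.n - n_old);
      if (disp > max_disp) max_disp = disp;
    }
    A_total += max_disp;
    // SPBs: tangential-plane force projection, then radial re-projection
    for (int s = 0; s < 2; ++s) {
      SPB& b = spb[s];
      Vec3 Ft = b.F - b.u * dot(b.F, b.u);
      Vec3 drift = Ft * (P.D_spb / P.kT * P.dt);
      double dn = norm(drift);
      if (dn > P.cap_trans) drift = drift * (P.cap_trans / dn);
      Vec3 p1, p2;
      perp_basis(b.u, p1, p2);
      double sd = std::sqrt(2.0 * P.D_spb * P.dt);
      Vec3 dx = drift + p1 * (sd * rng.rnorm()) + p2 * (sd * rng.rnorm());
      b.u = normalize(b.u + dx * (1.0 / P.R));
      // spin about the normal
      double dpsi = b.T_u / P.kT * P.D_spb_rot * P.dt +
                    std::sqrt(2.0 * P.D_spb_rot * P.dt) * rng.rnorm();
      b.e1 = normalize(b.e1 - b.u * dot(b.e1, b.u));
      b.e2 = cross(b.u, b.e1);
      Vec3 ne1 = b.e1 * std::cos(dpsi) + b.e2 * std::sin(dpsi);
      b.e2 = cross(b.u, ne1);
      b.e1 = ne1;
    }
  }

  void step() {
    compute_forces(NULL);
    update_stabilization();
    di_and_growth_step();
    xl_kmc_step();
    xl_diffusion_step();
    brownian_move();
    ++step_idx;
    t += P.dt;
  }

  // count-based and length-weighted interpolar fractions
  void interpolar_fraction(double& if_count, double& if_length) const {
    std::vector<char> engaged(mts.size(), 0);
    for (size_t q = 0; q < xls.size(); ++q) {
      const XL& x = xls[q];
      if (x.state != 2) continue;
      if (mts[x.mt[0]].spb != mts[x.mt[1]].spb) {
        engaged[x.mt[0]] = 1;
        engaged[x.mt[1]] = 1;
      }
    }
    int c = 0;
    double le = 0, lt = 0;
    for (size_t i = 0; i < engaged.size(); ++i) {
      c += engaged[i];
      lt += mts[i].L;
      if (engaged[i]) le += mts[i].L;
    }
    if_count = mts.empty() ? 0.0 : (double)c / (double)mts.size();
    if_length = lt > 0 ? le / lt : 0.0;
  }
};

List state_to_list(const Engine& e) {
  int n = (int)e.mts.size();
  NumericMatrix mt(n, 7);
  IntegerVector mstate(n), mspb(n), msite(n);
  for (int i = 0; i < n; ++i) {
    const MT& m = e.mts[i];
    mt(i, 0) = m.c.x; mt(i, 1) = m.c.y; mt(i, 2) = m.c.z;
    mt(i, 3) = m.n.x; mt(i, 4) = m.n.y; mt(i, 5) = m.n.z;
    mt(i, 6) = m.L;
    mstate[i] = m.state;
    mspb[i] = m.spb + 1;
    msite[i] = m.site + 1;
  }
  colnames(mt) = Rcpp::CharacterVector::create("cx", "cy", "cz", "nx", "ny",
                                               "nz", "length");
  int nx = (int)e.xls.size();
  NumericMatrix xm(nx, 5);
  IntegerVector xstate(nx), xmt0(nx), xmt1(nx);
  for (int i = 0; i < nx; ++i) {
    const XL& x = e.xls[i];
    xm(i, 0) = x.pos.x; xm(i, 1) = x.pos.y; xm(i, 2) = x.pos.z;
    xm(i, 3) = x.x[0]; xm(i, 4) = x.x[1];
    xstate[i] = x.state;
    xmt0[i] = x.mt[0] + 1;
    xmt1[i] = x.mt[1] + 1;
  }
  colnames(xm) = Rcpp::CharacterVector::create("px", "py", "pz", "x0", "x1");
  List spbs(2);
  for (int s = 0; s < 2; ++s) {
    spbs[s] = List::create(
        Rcpp::Named("u") = NumericVector::create(e.spb[s].u.x, e.spb[s].u.y,
                                                 e.spb[s].u.z),
        Rcpp::Named("e1") = NumericVector::create(e.spb[s].e1.x, e.spb[s].e1.y,
                                                  e.spb[s].e1.z),
        Rcpp::Named("e2") = NumericVector::create(e.spb[s].e2.x, e.spb[s].e2.y,
                                                  e.spb[s].e2.z));
  }
  return List::create(
      Rcpp::Named("time") = e.t, Rcpp::Named("spb") = spbs,
      Rcpp::Named("mt") = List::create(
          Rcpp::Named("geom") = mt, Rcpp::Named("state") = mstate,
          Rcpp::Named("spb") = mspb, Rcpp::Named("site") = msite),
      Rcpp::Named("xl") = List::create(
          Rcpp::Named("geom") = xm, Rcpp::Named("state") = xstate,
          Rcpp::Named("mt0") = xmt0, Rcpp::Named("mt1") = xmt1));
}

void state_from_list(Engine& e, const List& st) {
  List mtl = st["mt"], xll = st["xl"], spbs = st["spb"];
  NumericMatrix mt = mtl["geom"];
  IntegerVector mstate = mtl["state"], mspb = mtl["spb"], msite = mtl["site"];
  e.mts.resize(mt.nrow());
  for (int i = 0; i < mt.nrow(); ++i) {
    MT& m = e.mts[i];
    m.c = Vec3(mt(i, 0), mt(i, 1), mt(i, 2));
    m.n = normalize(Vec3(mt(i, 3), mt(i, 4), mt(i, 5)));
    m.L = mt(i, 6);
    m.state = mstate[i];
    m.spb = mspb[i] - 1;
    m.site = msite[i] - 1;
    m.F = Vec3(); m.T = Vec3(); m.f_ax = 0; m.stab = false;
  }
  NumericMatrix xm = xll["geom"];
  IntegerVector xstate = xll["state"], xmt0 = xll["mt0"], xmt1 = xll["mt1"];
  e.xls.resize(xm.nrow());
  for (int i = 0; i < xm.nrow(); ++i) {
    XL& x = e.xls[i];
    x.pos = Vec3(xm(i, 0), xm(i, 1), xm(i, 2));
    x.x[0] = xm(i, 3); x.x[1] = xm(i, 4);
    x.state = xstate[i];
    x.mt[0] = xmt0[i] - 1;
    x.mt[1] = xmt1[i] - 1;
  }
  for (int s = 0; s < 2; ++s) {
    List sp = spbs[s];
    NumericVector u = sp["u"], e1 = sp["e1"], e2 = sp["e2"];
    e.spb[s].u = normalize(Vec3(u[0], u[1], u[2]));
    e.spb[s].e1 = Vec3(e1[0], e1[1], e1[2]);
    e.spb[s].e2 = Vec3(e2[0], e2[1], e2[2]);
  }
  e.t = Rcpp::as<double>(st["time"]);
  e.build_pairs();
}

NumericVector vec_of(const Vec3& v) {
  return NumericVector::create(v.x, v.y, v.z);
}

}  // namespace

// [[Rcpp::export]]
List cpp_sim_init(List params, int seed) {
  Params P = parse_params(params);
  Engine e(P, (uint64_t)seed);
  e.init();
  return state_to_list(e);
}

// [[Rcpp::export]]
List cpp_sim_run(List params, int seed) {
  Params P = parse_params(params);
  Engine e(P, (uint64_t)seed);
  e.init();
  long n_steps = (long)std::llround(P.t_total / P.dt);
  long frame_every = (long)std::llround(P.frame_interval / P.dt);
  if (frame_every < 1) frame_every = 1;
  long n_frames = n_steps / frame_every + 1;
  NumericVector times(n_frames), sep(n_frames), iff(n_frames),
      iffl(n_frames), meanL(n_frames);
  IntegerVector nfree(n_frames), none(n_frames), ntwo(n_frames);
  NumericMatrix spb1(n_frames, 3), spb2(n_frames, 3);
  NumericMatrix mtL;
  IntegerMatrix mtS;
  if (P.record_detail) {
    mtL = NumericMatrix(n_frames, (int)e.mts.size());
    mtS = Rcpp::IntegerMatrix(n_frames, (int)e.mts.size());
  }
  long f = 0;
  for (long s = 0; s <= n_steps; ++s) {
    if (s % frame_every == 0 && f < n_frames) {
      times[f] = e.t;
      Vec3 d = e.spb[0].u * P.R - e.spb[1].u * P.R;
      sep[f] = norm(d);
      e.interpolar_fraction(iff[f], iffl[f]);
      double ml = 0;
      for (size_t i = 0; i < e.mts.size(); ++i) ml += e.mts[i].L;
      meanL[f] = ml / e.mts.size();
      int c0 = 0, c1 = 0, c2 = 0;
      for (size_t i = 0; i < e.xls.size(); ++i) {
        if (e.xls[i].state == 0) ++c0;
        else if (e.xls[i].state == 1) ++c1;
        else ++c2;
      }
      nfree[f] = c0; none[f] = c1; ntwo[f] = c2;
      for (int k = 0; k < 3; ++k) {
        spb1(f, k) = (&e.spb[0].u.x)[k] * P.R;
        spb2(f, k) = (&e.spb[1].u.x)[k] * P.R;
      }
      if (P.record_detail) {
        for (size_t i = 0; i < e.mts.size(); ++i) {
          mtL(f, (int)i) = e.mts[i].L;
          mtS(f, (int)i) = e.mts[i].state;
        }
      }
      if (!std::isfinite(sep[f]) || !std::isfinite(meanL[f]))
        Rcpp::stop("numerical blow-up at t=%f s", e.t);
      ++f;
    }
    if (s < n_steps) e.step();
    if (s % 50000 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(
      Rcpp::Named("time") = times, Rcpp::Named("separation") = sep,
      Rcpp::Named("interpolar_fraction") = iff,
      Rcpp::Named("interpolar_fraction_length") = iffl,
      Rcpp::Named("mean_mt_length") = meanL, Rcpp::Named("n_free") = nfree,
      Rcpp::Named("n_one_bound") = none, Rcpp::Named("n_two_bound") = ntwo,
      Rcpp::Named("spb1") = spb1, Rcpp::Named("spb2") = spb2,
      Rcpp::Named("cap_events") = (double)e.cap_events,
      Rcpp::Named("final_state") = state_to_list(e));
  if (P.record_detail) {
    out["mt_lengths"] = mtL;
    out["mt_states"] = mtS;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sim_forces(List params, List state) {
  Params P = parse_params(params);
  Engine e(P, 1u);
  state_from_list(e, state);
  ForceDecomp dec;
  e.compute_forces(&dec);
  int n = (int)e.mts.size();
  NumericMatrix ft(n, 3), fs(n, 3), fx(n, 3), fw(n, 3), tt(n, 3), ts(n, 3),
      tx(n, 3), tw(n, 3);
  NumericVector fax(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      ft(i, k) = (&dec.tether[i].x)[k];
      fs(i, k) = (&dec.steric[i].x)[k];
      fx(i, k) = (&dec.xlink[i].x)[k];
      fw(i, k) = (&dec.wall[i].x)[k];
      tt(i, k) = (&dec.t_tether[i].x)[k];
      ts(i, k) = (&dec.t_steric[i].x)[k];
      tx(i, k) = (&dec.t_xlink[i].x)[k];
      tw(i, k) = (&dec.t_wall[i].x)[k];
    }
    fax[i] = e.mts[i].f_ax;
  }
  return List::create(
      Rcpp::Named("mt_tether") = ft, Rcpp::Named("mt_steric") = fs,
      Rcpp::Named("mt_crosslink") = fx, Rcpp::Named("mt_wall") = fw,
      Rcpp::Named("torque_tether") = tt, Rcpp::Named("torque_steric") = ts,
      Rcpp::Named("torque_crosslink") = tx, Rcpp::Named("torque_wall") = tw,
      Rcpp::Named("axial_load") = fax,
      Rcpp::Named("spb_tether") = List::create(vec_of(dec.spb_tether[0]),
                                               vec_of(dec.spb_tether[1])),
      Rcpp::Named("spb_steric") = List::create(vec_of(dec.spb_steric[0]),
                                               vec_of(dec.spb_steric[1])),
      Rcpp::Named("spb_spin_torque") = NumericVector::create(
          dec.spb_torque[0], dec.spb_torque[1]));
}

// Crosslinker kinetics on frozen filaments: only kMC and head/free diffusion
// run; rod and SPB positions never move. Used for equilibrium-statistics
// validation against direct Boltzmann integration.
// [[Rcpp::export]]
List cpp_xl_equilibrium(List params, List state, double t_burn,
                        int n_samples, double sample_interval, int seed) {
  Params P = parse_params(params);
  Engine e(P, (uint64_t)seed);
  state_from_list(e, state);
  long burn_steps = (long)std::llround(t_burn / P.dt);
  long gap = (long)std::llround(sample_interval / P.dt);
  if (gap < 1) gap = 1;
  for (long s = 0; s < burn_steps; ++s) {
    e.xl_kmc_step();
    e.xl_diffusion_step();
    ++e.step_idx;
  }
  double occ0 = 0, occ1 = 0, occ2 = 0;
  std::vector<double> pos1, pos2a, pos2b;
  std::vector<int> pos1_mt;
  for (int smp = 0; smp < n_samples; ++smp) {
    for (long s = 0; s < gap; ++s) {
      e.xl_kmc_step();
      e.xl_diffusion_step();
      ++e.step_idx;
    }
    for (size_t i = 0; i < e.xls.size(); ++i) {
      const XL& x = e.xls[i];
      if (x.state == 0) ++occ0;
      else if (x.state == 1) {
        ++occ1;
        pos1.push_back(x.x[0]);
        pos1_mt.push_back(x.mt[0] + 1);
      } else {
        ++occ2;
        int a = x.mt[0] < x.mt[1] ? 0 : 1;
        pos2a.push_back(x.x[a]);
        pos2b.push_back(x.x[1 - a]);
      }
    }
    if (smp % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      Rcpp::Named("occupancy") = NumericVector::create(occ0, occ1, occ2),
      Rcpp::Named("one_bound_pos") = Rcpp::wrap(pos1),
      Rcpp::Named("one_bound_mt") = Rcpp::wrap(pos1_mt),
      Rcpp::Named("two_bound_pos_a") = Rcpp::wrap(pos2a),
      Rcpp::Named("two_bound_pos_b") = Rcpp::wrap(pos2b));
}
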