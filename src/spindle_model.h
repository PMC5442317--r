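#ifndef SPINDLE_MODEL_H
#define SPINDLE_MODEL_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "spindle_vec.h"

// Internal units: length um, time s, force pN, energy pN*um.
// The user-facing thermal_energy config key is in pN*nm (community convention
// kT = 4.11 pN nm) and is converted on parse.

struct Params {
  // geometry
  double R;            // envelope radius
  double r_spb;        // SPB disk radius
  double D_spb;        // SPB translational diffusion on the envelope
  double D_spb_rot;    // SPB spin diffusion about its normal (rad^2/s)
  double d_mt;         // MT diameter
  int sites_per_spb;
  double k_tether;
  double tether_rest;
  double L_init;
  double L_min;
  double eta;          // effective nucleoplasm viscosity (pN s / um^2)
  double k_ang;        // nucleation-site orientation stiffness (pN um / rad)
  double cone;         // nucleation cone spread (tangent of max tilt)

  // dynamic instability
  double v_g, v_s, f_c, f_r;
  bool force_catastrophe;      // stalled plus ends catastrophe faster
  double force_catastrophe_cap;

  // stabilization
  double s_vg, s_vs, s_fc, s_fr, s_len;
  bool stab_enabled;

  // crosslinkers
  int n_xl;
  double k_xl;
  double r0_xl;
  double k1_on;        // per (um of MT within capture) per s
  double k1_off;
  double k2_on;        // per um per s (partition-weight scale)
  double k2_off;
  double D_bound;
  double D_free;
  double ap_threshold; // crosslink allowed iff dot(n_a, n_b) < threshold
  double bell_x;       // Bell characteristic distance for force-dependent off
  double capture_radius;
  double quad_bin;     // quadrature bin for the pair partition integral
  double e_cut_kt;     // energy cutoff (kT units) for the integral window
  bool end_release;    // heads stepping past a lattice end fall off (else clamp)
  double minus_excl;   // minus-proximal arc length occluded for binding

  // wall force
  double F_w, R_tube, euler_gamma, const_a, const_c, blend_len;

  // ratchet
  int n_proto;
  double sigma;        // per-protofilament length increment (um)
  double F_s;          // stall-scale force
  double kT;           // pN*um

  // control
  double dt, t_total, frame_interval;
  double init_angle;   // initial pole arc separation (rad); 0 = adjacent
  bool record_detail;
  int xl_free_interval, xl_pair_interval, neighbor_interval;
  double cap_trans, cap_rot;
  double steric_eps_kt;
};

inline double get_num(const Rcpp::List& l, const char* name) {
  if (!l.containsElementNamed(name))
    Rcpp::stop(std::string("missing parameter field: ") + name);
  return Rcpp::as<double>(l[name]);
}
inline bool get_flag(const Rcpp::List& l, const char* name) {
  if (!l.containsElementNamed(name))
    Rcpp::stop(std::string("missing parameter field: ") + name);
  return Rcpp::as<bool>(l[name]);
}

inline Params parse_params(const Rcpp::List& p) {
  Params q;
  Rcpp::List g = p["geometry"], di = p["dynamic_instability"],
             st = p["stabilization"], xl = p["crosslinkers"],
             wf = p["wall_force"], rt = p["ratchet"], ct = p["control"];
  q.R = get_num(g, "envelope_diameter") / 2.0;
  q.r_spb = get_num(g, "spb_diameter") / 2.0;
  q.D_spb = get_num(g, "spb_diffusion_coefficient");
  q.D_spb_rot = get_num(g, "spb_rotational_diffusion");
  q.d_mt = get_num(g, "mt_diameter");
  q.sites_per_spb = (int)get_num(g, "sites_per_spb");
  q.k_tether = get_num(g, "tether_spring_constant");
  q.tether_rest = get_num(g, "tether_rest_length");
  q.L_init = get_num(g, "initial_mt_length");
  q.L_min = get_num(g, "min_mt_length");
  q.eta = get_num(g, "viscosity");
  q.k_ang = get_num(g, "nucleation_stiffness");
  q.cone = get_num(g, "nucleation_cone");

  q.v_g = get_num(di, "growth_speed");
  q.v_s = get_num(di, "shrinking_speed");
  q.f_c = get_num(di, "catastrophe_frequency");
  q.f_r = get_num(di, "rescue_frequency");
  q.force_catastrophe = get_flag(di, "force_catastrophe");
  q.force_catastrophe_cap = get_num(di, "force_catastrophe_cap");

  q.s_vg = get_num(st, "growth_factor");
  q.s_vs = get_num(st, "shrink_factor");
  q.s_fc = get_num(st, "catastrophe_factor");
  q.s_fr = get_num(st, "rescue_factor");
  q.s_len = get_num(st, "stabilization_length");

  q.n_xl = (int)get_num(xl, "number");
  q.k_xl = get_num(xl, "spring_constant");
  q.r0_xl = get_num(xl, "rest_length");
  q.k1_on = get_num(xl, "one_head_on_rate");
  q.k1_off = get_num(xl, "one_head_off_rate");
  q.k2_on = get_num(xl, "two_head_on_rate_scale");
  q.k2_off = get_num(xl, "two_head_off_rate");
  q.D_bound = get_num(xl, "bound_diffusion_coefficient");
  q.D_free = get_num(xl, "free_diffusion_coefficient");
  q.ap_threshold = get_num(xl, "antiparallel_threshold");
  q.bell_x = get_num(xl, "bell_parameter");
  q.capture_radius = get_num(xl, "capture_radius");
  q.quad_bin = get_num(xl, "quadrature_bin");
  q.e_cut_kt = get_num(xl, "energy_cutoff_kt");
  q.end_release = get_flag(xl, "end_release");
  q.minus_excl = get_num(xl, "minus_exclusion");

  q.F_w = get_num(wf, "asymptotic_force");
  q.R_tube = get_num(wf, "tube_radius");
  q.euler_gamma = get_num(wf, "euler_gamma");
  q.const_a = get_num(wf, "const_a");
  q.const_c = get_num(wf, "const_c");
  q.blend_len = get_num(wf, "blend_length");

  q.n_proto = (int)get_num(rt, "protofilament_count");
  q.sigma = get_num(rt, "subunit_increment");
  q.F_s = get_num(rt, "stall_scale");
  q.kT = get_num(rt, "thermal_energy") * 1e-3;  // pN nm -> pN um

  q.dt = get_num(ct, "timestep");
  q.init_angle = get_num(ct, "initial_pole_angle");
  q.t_total = get_num(ct, "total_time");
  q.frame_interval = get_num(ct, "frame_interval");
  q.stab_enabled = get_flag(ct, "stabilization_enabled");
  q.record_detail = get_flag(ct, "record_mt_detail");
  q.xl_free_interval = (int)get_num(ct, "xl_free_interval");
  q.xl_pair_interval = (int)get_num(ct, "xl_pair_interval");
  q.neighbor_interval = (int)get_num(ct, "neighbor_interval");
  q.cap_trans = get_num(ct, "max_step_translation");
  q.cap_rot = get_num(ct, "max_step_rotation");
  q.steric_eps_kt = get_num(ct, "steric_strength");
  return q;
}

// Nuclear-envelope wall force on a protruding MT plus tip.
// L = protrusion distance past the envelope (um), >= 0.
// Linear (small-deformation) membrane response blended with the
// non-monotonic membrane-tube regime; F(0) = 0 exactly, F -> F_w.
inline double wall_force_value(double L, double F_w, double R_tube,
                               double euler_gamma, double a, double c,
                               double blend_len, double r_mt) {
  if (L <= 0.0 || F_w <= 0.0) return 0.0;
  const double b = std::sqrt(2.0) * R_tube;
  double denom = std::log(2.0 * b / r_mt) - euler_gamma;
  if (denom < 0.1) denom = 0.1;
  const double f_lin = F_w * L / (2.0 * R_tube * denom);
  const double x = c * L / b;
  const double f_nm = F_w * (1.0 + a * std::exp(-x) * std::cos(x));
  return std::exp(-L / b) * f_lin + (1.0 - std::exp(-L / blend_len)) * f_nm;
}

// Multi-filament Brownian-ratchet growth speed under axial compressive load F.
// v(0) = v_g exactly; stalls at F = F_s.
inline double ratchet_speed(double F, double v_g, double F_s, double sigma,
                            double kT) {
  if (F <= 0.0) return v_g;
  if (F_s <= 0.0) return 0.0;
  const double alpha = std::exp(F_s * sigma / kT);
  const double beta = F * sigma / kT;
  const double v = v_g * (alpha * std::exp(-beta) - 1.0) / (alpha - 1.0);
  return v > 0.0 ? v : 0.0;
}

// slender-body drag coefficients for a rigid rod
inline void rod_drag(double L, double d, double eta, double& g_par,
                     double& g_perp, double& g_rot) {
  double Le = L < 2.0 * d ? 2.0 * d : L;  // mobility floor for stubs
  double lp = std::log(Le / d);
  g_par = 2.0 * M_PI * eta * Le / (lp - 0.207 + 0.980 / lp);
  g_perp = 4.0 * M_PI * eta * Le / (lp + 0.839 + 0.185 / lp);
  g_rot = M_PI * eta * Le * Le * Le / (3.0 * (lp - 0.662 + 0.917 / lp));
}

#endif
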