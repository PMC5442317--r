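// Auxiliary compiled kernels: the wall-force and ratchet laws exposed to R,
// single-MT dynamic instability ensembles, and free-rod diffusion sampling.

#include <Rcpp.h>
#include <vector>
#include "spindle_vec.h"
#include "spindle_rng.h"
#include "spindle_model.h"

using Rcpp::List;
using Rcpp::NumericVector;

// [[Rcpp::export]]
NumericVector cpp_wall_force(NumericVector L, double F_w, double R_tube,
                             double euler_gamma, double const_a,
                             double const_c, double blend_length,
                             double mt_radius) {
  NumericVector out(L.size());
  for (int i = 0; i < L.size(); ++i) {
    if (L[i] < 0) Rcpp::stop("protrusion distance must be >= 0");
    out[i] = wall_force_value(L[i], F_w, R_tube, euler_gamma, const_a,
                              const_c, blend_length, mt_radius);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ratchet_speed(NumericVector F, double v_g, double F_s,
                                double sigma, double kT_pNnm) {
  NumericVector out(F.size());
  double kT = kT_pNnm * 1e-3;
  for (int i = 0; i < F.size(); ++i)
    out[i] = ratchet_speed(F[i] < 0 ? 0 : F[i], v_g, F_s, sigma, kT);
  return out;
}

// Ensemble of independent MTs undergoing four-parameter dynamic instability,
// no boundary, no crosslinkers. Renucleation floor at L_min with immediate
// regrowth. Returns the ensemble/time-averaged length after burn-in, a mean
// length time series, final lengths, and switching waiting times.
// [[Rcpp::export]]
List cpp_mt_ensemble(double v_g, double v_s, double f_c, double f_r,
                     double dt, double t_burn, double t_measure, int n_mt,
                     double L_init, double L_min, double ts_interval,
                     int max_events, int seed) {
  Rng rng((uint64_t)seed);
  std::vector<double> L(n_mt, L_init);
  std::vector<int> st(n_mt, 1);
  std::vector<double> since_switch(n_mt, 0.0);
  const double p_cat = -std::expm1(-f_c * dt);
  const double p_res = -std::expm1(-f_r * dt);
  long burn_steps = (long)std::llround(t_burn / dt);
  long meas_steps = (long)std::llround(t_measure / dt);
  long ts_every = (long)std::llround(ts_interval / dt);
  if (ts_every < 1) ts_every = 1;
  std::vector<double> cat_wait, res_wait, ts_mean;
  cat_wait.reserve(max_events);
  res_wait.reserve(max_events);
  double acc = 0.0;
  long n_acc = 0;
  for (long s = 0; s < burn_steps + meas_steps; ++s) {
    bool measuring = s >= burn_steps;
    double msum = 0;
    for (int i = 0; i < n_mt; ++i) {
      double u = rng.runif();
      since_switch[i] += dt;
      if (st[i] == 1) {
        if (u < p_cat) {
          st[i] = -1;
          if (measuring && (int)cat_wait.size() < max_events)
            cat_wait.push_back(since_switch[i]);
          since_switch[i] = 0;
        }
      } else {
        if (u < p_res) {
          st[i] = 1;
          if (measuring && (int)res_wait.size() < max_events)
            res_wait.push_back(since_switch[i]);
          since_switch[i] = 0;
        }
      }
      if (st[i] == 1) {
        L[i] += v_g * dt;
      } else {
        L[i] -= v_s * dt;
        if (L[i] < L_min) {
          L[i] = L_min;
          st[i] = 1;
          since_switch[i] = 0;
        }
      }
      msum += L[i];
    }
    if (measuring) {
      acc += msum / n_mt;
      ++n_acc;
      if ((s - burn_steps) % ts_every == 0) ts_mean.push_back(msum / n_mt);
    }
    if (s % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      Rcpp::Named("mean_length") = n_acc ? acc / n_acc : NA_REAL,
      Rcpp::Named("final_lengths") = Rcpp::wrap(L),
      Rcpp::Named("mean_length_series") = Rcpp::wrap(ts_mean),
      Rcpp::Named("catastrophe_waits") = Rcpp::wrap(cat_wait),
      Rcpp::Named("rescue_waits") = Rcpp::wrap(res_wait));
}

// Free rigid rod, no forces: sample the integrator's effective diffusion
// coefficients from per-step displacements.
// [[Rcpp::export]]
List cpp_rod_diffusion(double L, double d_mt, double eta, double kT_pNnm,
                       double dt, int n_steps, int n_rep, int seed) {
  Rng rng((uint64_t)seed);
  double kT = kT_pNnm * 1e-3;
  double g_par, g_perp, g_rot;
  rod_drag(L, d_mt, eta, g_par, g_perp, g_rot);
  const double sd_par = std::sqrt(2.0 * kT * dt / g_par);
  const double sd_perp = std::sqrt(2.0 * kT * dt / g_perp);
  const double sd_rot = std::sqrt(2.0 * kT * dt / g_rot);
  double s_par = 0, s_perp = 0, s_rot = 0;
  long n = 0;
  for (int r = 0; r < n_rep; ++r) {
    Vec3 c(0, 0, 0);
    Vec3 nv = normalize(Vec3(rng.rnorm(), rng.rnorm(), rng.rnorm()));
    for (int s = 0; s < n_steps; ++s) {
      Vec3 p1, p2;
      perp_basis(nv, p1, p2);
      double dpar = sd_par * rng.rnorm();
      double dp1 = sd_perp * rng.rnorm(), dp2 = sd_perp * rng.rnorm();
      c += nv * dpar + p1 * dp1 + p2 * dp2;
      double r1 = sd_rot * rng.rnorm(), r2 = sd_rot * rng.rnorm();
      Vec3 nn = normalize(nv + p1 * r1 + p2 * r2);
      s_par += dpar * dpar;
      s_perp += dp1 * dp1 + dp2 * dp2;
      double ang2 = norm2(nn - nv);  // small-angle squared displacement
      s_rot += ang2;
      nv = nn;
      ++n;
    }
  }
  return List::create(
      Rcpp::Named("D_par_hat") = s_par / (2.0 * dt * n),
      Rcpp::Named("D_perp_hat") = s_perp / (4.0 * dt * n),
      Rcpp::Named("D_rot_hat") = s_rot / (4.0 * dt * n),
      Rcpp::Named("D_par") = kT / g_par, Rcpp::Named("D_perp") = kT / g_perp,
      Rcpp::Named("D_rot") = kT / g_rot);
}
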