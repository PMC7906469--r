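// Overdamped Langevin (Euler-Maruyama) integrator for the analytic toy
// potentials, with optional dual-boost bias.  Uses R's RNG so runs are
// reproducible from set.seed().
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Toy {
  int kind;           // 1 = double_well_1d, 2 = two_dim_surface, 3 = harmonic_1d
  double h, a, tilt;  // x double well (h = force constant for harmonic)
  double hd, ad, cxy; // y ("dihedral") well and coupling
  int dim() const { return kind == 2 ? 2 : 1; }
  static double dw(double x, double h, double a) {
    double u = (x / a) * (x / a) - 1.0;
    return h * u * u;
  }
  static double dwg(double x, double h, double a) {
    return 4.0 * h * x * (x * x - a * a) / (a * a * a * a);
  }
  double vtot(const double *x) const {
    if (kind == 3) return 0.5 * h * x[0] * x[0] + tilt * x[0];
    double v = dw(x[0], h, a) + tilt * x[0];
    if (kind == 2) v += dw(x[1], hd, ad) + cxy * x[0] * x[1];
    return v;
  }
  double vdih(const double *x) const {
    return kind == 2 ? dw(x[1], hd, ad) : 0.0;
  }
  void grad(const double *x, double *g) const {
    if (kind == 3) { g[0] = h * x[0] + tilt; return; }
    g[0] = dwg(x[0], h, a) + tilt;
    if (kind == 2) {
      g[0] += cxy * x[1];
      g[1] = dwg(x[1], hd, ad) + cxy * x[0];
    }
  }
  void grad_dih(const double *x, double *g) const {
    g[0] = 0.0;
    if (kind == 2) g[1] = dwg(x[1], hd, ad); else return;
  }
};

// boost value and force scale for one channel; returns value, sets scale
inline double channel(double V, double E, double alpha, double *scale) {
  if (!(V < E)) { *scale = 1.0; return 0.0; }
  double gap = E - V, den = alpha + gap;
  *scale = alpha * alpha / (den * den);
  return gap * gap / den;
}

} // namespace

// [[Rcpp::export]]
List cpp_sample_langevin(int kind, NumericVector params, NumericVector x0,
                         double dt, int n_steps, double friction, double kT,
                         double E_p, double alpha_p, double E_d, double alpha_d,
                         int burn_in, int save_every) {
  Toy pot{kind, params[0], params[1], params[2], params[3], params[4], params[5]};
  const int d = pot.dim();
  const bool use_p = R_finite(E_p), use_d = R_finite(E_d);
  const double mob = dt / friction;
  const double noise = std::sqrt(2.0 * kT * dt / friction);

  int n_save = (n_steps - burn_in) / save_every;
  NumericMatrix pos(n_save, d);
  NumericVector V(n_save), Vd(n_save), dV(n_save);

  double x[2] = {x0[0], d == 2 ? x0[1] : 0.0};
  double g[2], gd[2];
  int isave = 0, error_frame = -1;

  RNGScope scope;
  for (int step = 0; step < n_steps; ++step) {
    double v = pot.vtot(x);
    double vd = pot.vdih(x);
    if (!R_finite(v) || std::fabs(v) > 1e12) { error_frame = step; break; }
    double sp = 1.0, sd = 1.0;
    if (use_p) channel(v, E_p, alpha_p, &sp);
    if (use_d) channel(vd, E_d, alpha_d, &sd);
    pot.grad(x, g);
    if (d == 2 && use_d) pot.grad_dih(x, gd); else { gd[0] = gd[1] = 0.0; }
    for (int k = 0; k < d; ++k) {
      // d/dx [V + dVp(V) + dVd(Vd)] = sp * grad V + (sd - 1) * grad Vd
      double force = sp * g[k] + (sd - 1.0) * gd[k];
      x[k] += -mob * force + noise * norm_rand();
    }
    if (step >= burn_in && (step - burn_in + 1) % save_every == 0 && isave < n_save) {
      for (int k = 0; k < d; ++k) pos(isave, k) = x[k];
      double vv = pot.vtot(x), vvd = pot.vdih(x);
      double s;
      V[isave] = vv;
      Vd[isave] = vvd;
      dV[isave] = (use_p ? channel(vv, E_p, alpha_p, &s) : 0.0) +
                  (use_d ? channel(vvd, E_d, alpha_d, &s) : 0.0);
      ++isave;
    }
  }
  if (error_frame < 0 && isave < n_save) {
    pos = pos(Range(0, std::max(isave - 1, 0)), _);
  }
  return List::create(_["positions"] = pos, _["V"] = V, _["Vd"] = Vd,
                      _["dV"] = dV, _["error_frame"] = error_frame);
}
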