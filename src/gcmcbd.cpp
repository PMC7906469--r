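// Simplified grand canonical Monte Carlo / Brownian dynamics permeation
// simulator.  Ions are ideal (no ion-ion forces) and move by overdamped
// Euler-Maruyama in a static channel model: hard-wall membrane slab with a
// pore of tabulated radius r(z) (optionally with a concentric hard
// obstacle), a smooth axial energy well per species inside the pore, and a
// linear voltage ramp across the membrane.  GCMC insertions/deletions in
// the two buffer slabs at the +/-z box ends clamp the reservoir
// concentration (ideal-gas acceptance, Poisson-count detailed balance).
// Uses R's RNG throughout for set.seed() reproducibility.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  double Lx, Ly, Lz;        // box, Angstrom; z in [-Lz/2, Lz/2]
  double half_mem;          // membrane spans [-half_mem, half_mem]
  std::vector<double> rz;   // pore radius tabulated across the membrane
  double grid;              // z spacing of rz
  double obstacle_r_frac;   // concentric hard post: r < frac * r(z) blocked
  double volt_kcal[2];      // q_s * V in kcal/mol (full drop across membrane)
  double well[2];           // well depth per species (kcal/mol, >0 attractive)
  double well_sigma;        // axial Gaussian width of the well

  double radius_at(double z) const {
    double u = (z + half_mem) / grid;
    int i = (int)u;
    if (i < 0) i = 0;
    int n = (int)rz.size();
    if (i >= n - 1) return rz[n - 1];
    double f = u - i;
    return rz[i] * (1 - f) + rz[i + 1] * f;
  }
  bool blocked(double x, double y, double z) const {
    if (z < -half_mem || z > half_mem) return false;
    double r = std::sqrt(x * x + y * y);
    double R = radius_at(z);
    if (r > R) return true;
    if (obstacle_r_frac > 0 && r < obstacle_r_frac * R) return true;
    return false;
  }
  // energy derivative dU/dz for species s (x,y carry no force; steric is
  // handled by move rejection)
  double dUdz(int s, double z) const {
    double g = 0.0;
    if (z > -half_mem && z < half_mem) {
      g += volt_kcal[s] / (2.0 * half_mem);                 // linear ramp
      double sg = well_sigma;
      g += well[s] * z / (sg * sg) * std::exp(-0.5 * z * z / (sg * sg));
    }
    return g;
  }
};

inline double reflect(double v, double lo, double hi) {
  double span = hi - lo, span2 = 2 * span;
  v = v - lo;
  v -= span2 * std::floor(v / span2);
  return lo + (v > span ? span2 - v : v);
}

} // namespace

// [[Rcpp::export]]
List cpp_run_gcmcbd(NumericVector box, double half_mem, NumericVector rz,
                    double grid, double obstacle_r_frac,
                    NumericVector volt_kcal, NumericVector well,
                    double well_sigma, NumericVector D_A2ps, double kT,
                    double dt_ps, double buffer, double nbar_buffer,
                    int cycles, int gcmc_per_step, int trace_every,
                    int pos_trace_every, int capacity) {
  Model mod;
  mod.Lx = box[0]; mod.Ly = box[1]; mod.Lz = box[2];
  mod.half_mem = half_mem;
  mod.rz.assign(rz.begin(), rz.end());
  mod.grid = grid;
  mod.obstacle_r_frac = obstacle_r_frac;
  mod.volt_kcal[0] = volt_kcal[0]; mod.volt_kcal[1] = volt_kcal[1];
  mod.well[0] = well[0]; mod.well[1] = well[1];
  mod.well_sigma = well_sigma;

  const double zlo = -mod.Lz / 2, zhi = mod.Lz / 2;
  const double buf_lo_edge = zlo + buffer;   // bottom buffer: [zlo, buf_lo_edge]
  const double buf_hi_edge = zhi - buffer;   // top buffer: [buf_hi_edge, zhi]

  // per-slot state
  std::vector<int> species(capacity, -1);    // -1 = empty slot
  std::vector<double> px(capacity), py(capacity), pz(capacity);
  std::vector<int> cstate(capacity);         // 1 below, 2 inside, 3 above
  std::vector<int> corigin(capacity);

  RNGScope scope;

  auto region = [&](double z) { return z < -half_mem ? 1 : (z > half_mem ? 3 : 2); };
  auto in_buffer = [&](double z) { return z <= buf_lo_edge ? 0 : (z >= buf_hi_edge ? 1 : -1); };

  // initial fill: Poisson-ish via nbar acceptance would take time to
  // equilibrate; start with round(nbar) ions per species per buffer plus a
  // uniform bulk population at the same concentration
  double conc = nbar_buffer / (mod.Lx * mod.Ly * buffer);
  int ins_init[2][2];
  int n_active = 0;
  auto place = [&](int s, double z0, double z1) {
    for (int k = 0; k < capacity; ++k) if (species[k] < 0) {
      double x, y, z;
      int guard = 0;
      do {
        x = unif_rand() * mod.Lx - mod.Lx / 2;
        y = unif_rand() * mod.Ly - mod.Ly / 2;
        z = z0 + unif_rand() * (z1 - z0);
      } while (mod.blocked(x, y, z) && ++guard < 100);
      if (guard >= 100) return;
      species[k] = s; px[k] = x; py[k] = y; pz[k] = z;
      cstate[k] = region(z); corigin[k] = cstate[k] == 2 ? 0 : cstate[k];
      ++n_active;
      return;
    }
  };
  for (int s = 0; s < 2; ++s) {
    int nbuf = (int)std::lround(nbar_buffer);
    for (int b = 0; b < 2; ++b) {
      ins_init[s][b] = nbuf;
      for (int k = 0; k < nbuf; ++k)
        place(s, b == 0 ? zlo : buf_hi_edge, b == 0 ? buf_lo_edge : zhi);
    }
    // bulk between the buffers (membrane region included where allowed)
    double vol_mid = mod.Lx * mod.Ly * (buf_hi_edge - buf_lo_edge);
    int nmid = (int)std::lround(conc * vol_mid);
    for (int k = 0; k < nmid; ++k) place(s, buf_lo_edge, buf_hi_edge);
  }
  (void)ins_init;

  // bookkeeping
  long crossings[2][2] = {{0, 0}, {0, 0}};   // [species][dir: 0 = -z, 1 = +z]
  long insertions[2][2] = {{0, 0}, {0, 0}};  // [buffer][species]
  long deletions[2][2] = {{0, 0}, {0, 0}};
  long net_entries[2][2] = {{0, 0}, {0, 0}}; // BD moves into buffer (net)
  int n0_buf[2][2];                          // counts at trace start
  for (int b = 0; b < 2; ++b) for (int s = 0; s < 2; ++s) n0_buf[b][s] = 0;
  for (int k = 0; k < capacity; ++k) if (species[k] >= 0) {
    int b = in_buffer(pz[k]);
    if (b >= 0) ++n0_buf[b][species[k]];
  }

  int n_trace = trace_every > 0 ? cycles / trace_every : 0;
  NumericMatrix conc_trace(n_trace, 5); // cycle, bottom K, bottom Cl, top K, top Cl
  int n_ptrace = pos_trace_every > 0 ? cycles / pos_trace_every : 0;
  NumericVector pos_trace(n_ptrace > 0 ? (R_xlen_t)n_ptrace * capacity * 3 : 0);
  if (n_ptrace > 0) std::fill(pos_trace.begin(), pos_trace.end(), NA_REAL);

  double sigma[2] = {std::sqrt(2 * D_A2ps[0] * dt_ps), std::sqrt(2 * D_A2ps[1] * dt_ps)};
  double mob[2] = {D_A2ps[0] * dt_ps / kT, D_A2ps[1] * dt_ps / kT};

  for (int cyc = 0; cyc < cycles; ++cyc) {
    // --- BD step for every active ion ---
    for (int k = 0; k < capacity; ++k) {
      int s = species[k];
      if (s < 0) continue;
      double fz = -mod.dUdz(s, pz[k]);
      double nx = px[k] + sigma[s] * norm_rand();
      double ny = py[k] + sigma[s] * norm_rand();
      double nz = pz[k] + mob[s] * fz + sigma[s] * norm_rand();
      nx = reflect(nx, -mod.Lx / 2, mod.Lx / 2);
      ny = reflect(ny, -mod.Ly / 2, mod.Ly / 2);
      nz = reflect(nz, zlo, zhi);
      if (mod.blocked(nx, ny, nz)) continue;  // hard-wall rejection
      int b_old = in_buffer(pz[k]), b_new = in_buffer(nz);
      if (b_old != b_new) {
        if (b_new >= 0) ++net_entries[b_new][s];
        if (b_old >= 0) --net_entries[b_old][s];
      }
      px[k] = nx; py[k] = ny; pz[k] = nz;
      int r = region(nz);
      if (cstate[k] != 2) {
        if (r == 2) { corigin[k] = cstate[k]; cstate[k] = 2; }
        else if (r != cstate[k]) { cstate[k] = r; corigin[k] = r; }
      } else if (r != 2) {
        if (corigin[k] != 0 && r != corigin[k])
          ++crossings[s][r == 3 ? 1 : 0];
        cstate[k] = r; corigin[k] = r;
      }
    }
    // --- GCMC: one attempt per buffer per species per step ---
    for (int rep = 0; rep < gcmc_per_step; ++rep)
    for (int b = 0; b < 2; ++b) {
      for (int s = 0; s < 2; ++s) {
        int nbuf = 0;
        for (int k = 0; k < capacity; ++k)
          if (species[k] == s && in_buffer(pz[k]) == b) ++nbuf;
        if (unif_rand() < 0.5) {
          // insertion
          double acc = nbar_buffer / (nbuf + 1);
          if (unif_rand() < std::min(1.0, acc)) {
            for (int k = 0; k < capacity; ++k) if (species[k] < 0) {
              px[k] = unif_rand() * mod.Lx - mod.Lx / 2;
              py[k] = unif_rand() * mod.Ly - mod.Ly / 2;
              pz[k] = b == 0 ? zlo + unif_rand() * buffer
                             : zhi - buffer + unif_rand() * buffer;
              species[k] = s;
              cstate[k] = region(pz[k]);
              corigin[k] = cstate[k] == 2 ? 0 : cstate[k];
              ++insertions[b][s]; ++n_active;
              break;
            }
          }
        } else if (nbuf > 0) {
          // deletion of a uniformly chosen buffer ion
          double acc = (double)nbuf / nbar_buffer;
          if (unif_rand() < std::min(1.0, acc)) {
            int pick = (int)(unif_rand() * nbuf);
            for (int k = 0; k < capacity; ++k)
              if (species[k] == s && in_buffer(pz[k]) == b && pick-- == 0) {
                species[k] = -1; ++deletions[b][s]; --n_active;
                break;
              }
          }
        }
      }
    }
    if (trace_every > 0 && (cyc + 1) % trace_every == 0) {
      int row = (cyc + 1) / trace_every - 1;
      int cnt[2][2] = {{0, 0}, {0, 0}};
      for (int k = 0; k < capacity; ++k) if (species[k] >= 0) {
        int b = in_buffer(pz[k]);
        if (b >= 0) ++cnt[b][species[k]];
      }
      conc_trace(row, 0) = cyc + 1;
      conc_trace(row, 1) = cnt[0][0]; conc_trace(row, 2) = cnt[0][1];
      conc_trace(row, 3) = cnt[1][0]; conc_trace(row, 4) = cnt[1][1];
    }
    if (pos_trace_every > 0 && (cyc + 1) % pos_trace_every == 0) {
      int row = (cyc + 1) / pos_trace_every - 1;
      for (int k = 0; k < capacity; ++k) if (species[k] >= 0) {
        R_xlen_t base = ((R_xlen_t)row) + (R_xlen_t)n_ptrace * 3 * k;
        pos_trace[base] = px[k];
        pos_trace[base + n_ptrace] = py[k];
        pos_trace[base + 2 * (R_xlen_t)n_ptrace] = pz[k];
      }
    }
    if ((cyc & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  int nend_buf[2][2] = {{0, 0}, {0, 0}};
  for (int k = 0; k < capacity; ++k) if (species[k] >= 0) {
    int b = in_buffer(pz[k]);
    if (b >= 0) ++nend_buf[b][species[k]];
  }

  IntegerMatrix cross(2, 2), ins(2, 2), del(2, 2), nete(2, 2), n0(2, 2), n1(2, 2);
  for (int a = 0; a < 2; ++a) for (int b2 = 0; b2 < 2; ++b2) {
    cross(a, b2) = (int)crossings[a][b2];
    ins(a, b2) = (int)insertions[a][b2];
    del(a, b2) = (int)deletions[a][b2];
    nete(a, b2) = (int)net_entries[a][b2];
    n0(a, b2) = n0_buf[a][b2];
    n1(a, b2) = nend_buf[a][b2];
  }
  return List::create(
    _["crossings"] = cross,          // rows species (K, Cl), cols dir (-z, +z)
    _["insertions"] = ins,           // rows buffer (bottom, top), cols species
    _["deletions"] = del,
    _["net_entries"] = nete,
    _["buffer_n_start"] = n0,
    _["buffer_n_end"] = n1,
    _["conc_trace"] = conc_trace,
    _["pos_trace"] = pos_trace,
    _["n_pos_trace"] = n_ptrace,
    _["capacity"] = capacity,
    _["slot_species_end"] = IntegerVector(species.begin(), species.end()),
    _["n_active_end"] = n_active);
}
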