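# idrchannel

Desk-scale R toolkit for two linked problems in the computational study of
intrinsically disordered channel segments — exemplified by the N-terminus
(M1–G25) of the voltage-dependent anion channel, whose rearrangements
inside the β-barrel modulate ion flow:

1. **Sampling and un-biasing disordered ensembles.**  Dual-boost
   accelerated-dynamics biasing adds a non-negative boost
   ΔV = (E_p − V)²/(α_p + E_p − V) + (E_d − V_d)²/(α_d + E_d − V_d)
   whenever an energy channel falls below its threshold, with the standard
   size rules E_p = E_p0 + 0.16·n_atoms, α_p = 0.16·n_atoms,
   E_d = E_d0 + 3.5·n_res + 30·n_lip, α_d = 0.2·(3.5·n_res + 30·n_lip)
   (kcal/mol).  Unbiased averages and potentials of mean force are
   recovered with Maclaurin-truncated Boltzmann reweighting,
   w = Σ_{k≤10} (ΔV/k_BT)^k / k!, which trades a bounded truncation error
   for immunity to exponential noise amplification.

2. **Quantifying permeation.**  Complete ion traversals of the membrane
   slab are detected by a hysteretic state machine; current is the slope
   of the cumulative signed-transfer curve (1 e/ns = 160.2177 pA) scaled
   by the bulk-diffusion ratio D_exp/D_sim; conductance is G = I/V and
   selectivity the Cl⁻/K⁺ flux ratio.  A simplified grand canonical Monte
   Carlo / Brownian dynamics simulator screens static channel models
   (hard-wall pore profile, smooth wells, linear voltage ramp; ideal
   ions) against steric and electrostatic perturbations.

Around these sit the supporting ensemble statistics (Kabsch
superposition, RMSD/RMSF/Rg, RMSD-threshold clustering with medoids and
convergence curves, helix propensity, barrel ellipticity), ensemble
chemical-shift averaging scored against experiment (per-nucleus RMSE and
Pearson R), and ground-truthed synthetic generators (toy-potential
Langevin sampler, peptide ensembles with controllable helicity,
drift–diffusion ion boxes, noisy shift tables) that make every stage
testable without any external data.  See the methods vignette
(`vignettes/idrchannel-methods.Rmd`) for models, assumptions and design
decisions.

## Worked example

Bias a tilted double well, reweight it back, and compare the well
free-energy gap with direct numerical quadrature of the stated potential:

```r
library(idrchannel)
pot  <- toy_potential("double_well_1d", barrier = 2, tilt = 0.4)
bias <- boost_parameters(E_p = potential_energy(pot, 0) + 1, alpha_p = 2)
run  <- sample_langevin(pot, sampler_config(n_steps = 1e6, seed = 1,
                                            burn_in = 5e4), bias = bias)
w    <- maclaurin_weights(run$boosts, kT = kT_kcal(), k_max = 10)
well_free_energy_gap(run, weights = w)
-kT_kcal() * log(boltzmann_well_ratio(pot))
```

```
Langevin run: 950000 frames (1D), dual-boost biased, kT = 0.5925 kcal/mol
  mean boost dV = 1.228 kcal/mol (max 2.145)
reweighted well gap: -0.705 kcal/mol
quadrature reference: -0.733 kcal/mol
```

The biased run crosses the barrier roughly five times as often as an
unbiased one, yet the rank-10 reweighting recovers the equilibrium gap to
within sampling error (~0.05 kT here).

Permeation on a synthetic anion-selective trajectory:

```r
sp   <- data.frame(species = c("K", "CL"), charge = c(1, -1),
                   count = c(25, 25), D_cm2s = c(1.96e-5, 2.03e-5),
                   drift_A_ns = c(-2, 8))
traj <- generate_ion_trajectory(ion_box_spec(species = sp, frames = 4000,
                                             dt_ns = 0.05, seed = 2))
rep  <- estimate_current(detect_crossings(traj),
                         scaling = diffusion_scaling(), voltage_mV = 40)
rep
```

```
Crossing events: 854 over 200 ns (CL: 284 up / 115 down; K: 205 up / 250 down)
Current report (least_squares): slope -1.104 e/ns, factor 0.586 -> I = 103.669 pA
  at +40 mV -> G = 2.592 nS
  R^2 = 0.9950
  anion/cation ratio = 3.76
```

The slope is the net signed charge-transfer rate along z; the factor
0.586 is D_exp/D_sim for bulk KCl (1.918/3.273 × 10⁻⁵ cm²/s); current is
reported positive for passive transport toward the low-potential side, so
G = I/V stays positive at either polarity.  The anion/cation ratio is the
net Cl⁻ flux over the net K⁺ flux.

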