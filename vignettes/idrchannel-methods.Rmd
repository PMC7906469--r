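---
title: "Biased-sampling reweighting and channel permeation at desk scale"
author: "idrchannel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biased-sampling reweighting and channel permeation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrchannel)
```

## Scope and scientific background

Voltage-dependent anion channels (VDAC) carry a short N-terminal segment
(M1--G25) that behaves as an intrinsically disordered region in isolation:
13 of its 25 residues belong to the classic disorder-promoting set
{G, A, S, P, R, Q, E, K}, and in solution the free peptide shows almost no
persistent secondary structure.  Studying how such a segment samples its
conformational landscape, and how its rearrangements throttle ion flow
through the \eqn{\beta}-barrel, requires three methodological ingredients
that this package implements as tested, desk-scale components:

1. **Dual-boost accelerated-dynamics biasing and its inversion.**  A
   non-negative boost
   \deqn{\Delta V = \frac{(E_p - V)^2}{\alpha_p + E_p - V} +
         \frac{(E_d - V_d)^2}{\alpha_d + E_d - V_d}}
   is added whenever the total potential \eqn{V} (or the dihedral energy
   \eqn{V_d}) falls below its threshold, flattening barriers.  Thresholds
   and coefficients follow the standard per-system-size rules
   (`amd_parameters()`): \eqn{E_p = E_{p,0} + 0.16\,n_{atoms}},
   \eqn{\alpha_p = 0.16\,n_{atoms}};
   \eqn{E_d = E_{d,0} + 3.5\,n_{res} + 30\,n_{lip}},
   \eqn{\alpha_d = 0.2(3.5\,n_{res} + 30\,n_{lip})} (kcal/mol).
   Unbiased statistics are recovered by Boltzmann reweighting with the
   Maclaurin-truncated weight
   \eqn{w = \sum_{k=0}^{10} (\Delta V/k_BT)^k / k!}
   (`maclaurin_weights()`), which suppresses the exponential noise
   amplification of the exact weight \eqn{e^{\Delta V/k_BT}} at the cost
   of a small, analytically bounded truncation error (relative error
   \eqn{< 5\times10^{-4}} for \eqn{\Delta V \le 3\,k_BT}).

2. **Ensemble observables.**  Optimal rigid superposition (Kabsch, proper
   rotations only), RMSD/RMSF/radius of gyration, potentials of mean force
   \eqn{-k_BT\ln(\rho/\rho_{max})} over collective variables,
   RMSD-threshold agglomerative clustering with medoid representatives and
   cluster-count convergence curves, per-residue helix propensity, and
   barrel ellipticity \eqn{e = 1 - b/a} from a principal-component fit of
   ring projections.

3. **Permeation estimation.**  Complete ion traversals of the membrane
   slab are detected with a hysteretic three-state machine; the current is
   the slope of the cumulative signed charge-transfer curve
   (1 e/ns = 160.2177 pA) multiplied by the bulk-diffusion scaling factor
   \eqn{D_{exp}/D_{sim}}; conductance is \eqn{I/V} and anion/cation
   selectivity the ratio of species fluxes.  A simplified grand canonical
   Monte Carlo / Brownian dynamics simulator (`run_gcmcbd()`) reproduces
   the protocol shape of continuum permeation screens: Brownian ions in a
   static channel model with reservoir buffers clamped at a target
   concentration.

All-atom force fields, explicit solvent, neural-network chemical-shift
prediction and Poisson--Boltzmann grid solvers are out of scope; shift
predictions enter as tables and channel potentials as analytic profiles.

## Conventions

One table fixes every unit and sign choice (`unit_conventions()`):
lengths in Å, energies in kcal/mol, times in ns (BD steps in ps), charges
in elementary charges; \eqn{k_BT = 0.5925} kcal/mol at 298 K; the membrane
normal is z and the positive-voltage (cis) side is +z; 1 e/ns = 160.2177
pA; current is positive when net positive charge moves from the
positive-voltage side to the other side, so passive transport always
yields \eqn{G = I/V > 0}.  Crossing records additionally store the raw
signed transfer (charge × z-direction) for bookkeeping.

## Synthetic generators as study conditions

Every downstream stage is exercised on generators with known ground
truth; their defaults are the package's study conditions and are not
tuned per test.

**Toy potentials and the Langevin sampler.**  Overdamped Euler--Maruyama
dynamics (`sample_langevin()`, compiled core) on analytic potentials: a
tilted double well \eqn{h((x/a)^2-1)^2 + cx} (default barrier 3 kcal/mol,
separation 1, used with barrier 2 and tilt 0.4 in the recovery studies, a
regime with a few hundred spontaneous barrier crossings per 10^6 steps), a
2D surface whose y-term is designated the "dihedral" energy channel so the
dual-boost code path is exercised without torsion machinery, and a
harmonic well for closed-form variance checks.  Only equilibrium sampling
statistics matter for reweighting, so thermostats/barostats beyond
overdamped Langevin are deliberately absent.  Biased forces use the exact
boost-corrected gradient: the total-potential channel rescales the full
gradient by \eqn{\alpha^2/(\alpha+E-V)^2}, the dihedral channel rescales
its own term.

**Peptide ensembles.**  Per frame, a two-state Markov chain along the
residues (stationary helix probability, persistence 0.9 by default, so
helical runs are long compared to the 3-residue classifier stretch)
assigns helix/coil labels; C\eqn{\alpha} coordinates are built from fixed
3.8-Å virtual bonds, a 91° virtual bond angle and per-residue virtual
torsions: 52° when helical, otherwise drawn extended-dominated
(\eqn{|\tau| \in} 100--180°).  The extended coil choice is deliberate:
with no excluded volume a uniformly random torsion chain collapses to a
radius of gyration *below* the helical rod, whereas real disordered
chains are expanded; restricting coil torsions to the trans region
restores the physically expected ordering (helix \eqn{R_g <} coil
\eqn{R_g}).  Isotropic coordinate jitter (default \eqn{\sigma} = 0.15 Å)
adds frame-level noise; it propagates to ±4.5° of torsion noise, which
sets the helix classifier window at ±15° around the helical torsion
(37--67°), about three standard deviations, so genuinely helical residues
are rarely rejected while coil torsions never enter the window.  What the
generator does **not** emulate: side chains, excluded volume, sequence
heterogeneity and hydrogen-bond cooperativity — so passing recovery tests
demonstrates the estimators, not force-field realism.

**Ion boxes.**  Brownian displacements with per-species diffusion
coefficients (default K⁺ 1.96×10⁻⁵, Cl⁻ 2.03×10⁻⁵ cm²/s at the package's
150 mM KCl conditions) plus optional drift, either confined to the
membrane slab (field-driven transport) or applied everywhere (a conveyor
whose crossing rate is exactly \eqn{N v_z / L_z}, the bookkeeping
oracle).  z is periodic, x/y reflective; unwrapped coordinates are kept
for MSD estimation.  Defaults mirror the channel-box geometry
(85 × 85 × 95 Å, slab ±17.5 Å).

**Shift tables.**  Frame-level shifts are truth plus iid Gaussian noise;
the truth table is returned so ensemble averaging and RMSE/Pearson
scoring can be checked against closed forms.

## Numerical choices

* Maclaurin weights are accumulated in ascending rank with a running
  factorial; with the non-negative boost domain and even top rank the
  partial sums are positive (asserted, not assumed).
* PMF cells that are never visited are reported as `NA`, never `+Inf`,
  keeping surfaces serializable; the minimum occupied cell defines zero.
  Default bin width 0.5 Å for RMSD/Rg axes, configurable.
* Pairwise RMSD is exact O(n²) with per-pair Kabsch superposition
  (singular-value form with determinant correction; reflections are never
  returned); intended scale is ≤ ~3000 frames.
* Hierarchical clustering uses average linkage by default
  (complete-linkage by option); "plateau" of the cluster-count curve is
  reported as growth ≤ 2% of the total count over the trailing 25% of
  frames, and is diagnostic only.
* The crossing state machine requires an ion to clear the slab edge by a
  2-Å hysteresis buffer before an outer state is assigned, suppressing
  double counts from thermal recrossing; z-jumps larger than half the box
  are wraps, never traversals.  The midplane-passage frame of a traversal
  is the first frame past \eqn{(z_{lo}+z_{hi})/2} within the recorded
  crossing.
* RMSF superposes every frame on an iteratively refined mean structure
  (two passes); absorbing the six rigid degrees of freedom biases RMSF
  low by \eqn{\approx\sqrt{1 - 6/(3N)}}, which is why recovery checks use
  chains of ≥ 60 sites.
* MSD-based diffusion uses all unwrapped axes, a least-squares slope over
  the requested lag range, and a convexity flag against ballistic
  signatures.

## The GCMC/BD simplification

The simulator propagates *ideal* ions — no ion–ion or dielectric-boundary
forces — in a static channel model: hard-wall membrane slab (default 35 Å
in an 85 × 85 × 95 Å box) with a pore of tabulated radius r(z) on a 0.5-Å
grid, optional per-species smooth axial energy wells, and a linear
voltage ramp across the membrane.  Grand canonical insertions/deletions
in the two 5-Å buffer slabs use the ideal-gas acceptance
(\eqn{\min(1, \bar N/(N+1))} insert, \eqn{\min(1, N/\bar N)} delete,
\eqn{\bar N} the target count at 150 mM), whose stationary distribution
is Poisson at the target concentration — with zero excess chemical
potential this is exact for ideal ions.  One GCMC sweep (one attempt per
buffer per species) runs per BD step; hard-wall collisions are resolved
by move rejection; the exact bookkeeping identity
(count change = insertions − deletions + net boundary entries) is
asserted on every run.  Default 10⁶ cycles at desk scale (the cycle count
is configuration).  The omission of ion–ion forces is the principal
fidelity gap: absolute conductances of real channels are not claimed, and
the reference point for validation is instead the 1D Nernst--Planck
closed form for an ideal cylinder,
\eqn{G = \sum_s q^2 D_s c A / (k_BT L)}.  A wide-pore run approaches that
bound from below; the residual few-percent deficit is the lateral access
resistance between the buffer plane and the pore mouth plus hard-wall
step artifacts, both of which shrink with pore radius / step size.
Steric occlusion (a concentric hard post) strictly reduces conductance —
the qualitative mechanism by which a repositioned disordered segment
throttles the pore.

## Design decisions that were genuinely open

* **Threshold semantics of the dual boost:** each channel tests its own
  threshold (\eqn{E_p} against \eqn{V}, \eqn{E_d} against \eqn{V_d});
  this matches the two-term structure of the boost and the dual-boost
  literature.
* **Reference energies** \eqn{E_{p,0}, E_{d,0}} are means over an
  unbiased series after a configurable burn-in (default 10%); no
  published rule fixes the burn-in, so it is exposed rather than guessed.
* **Weighted standard errors** use the Kish effective sample size
  \eqn{(\sum w)^2/\sum w^2}; reweighted quantities need uncertainties for
  testable tolerances even though none are standard in this setting.
* **Ellipticity convention:** \eqn{a,b = \sqrt{2\lambda_{1,2}}} of the
  2D PCA and \eqn{e = 1-b/a}, on user-supplied ring anchors.  Published
  per-state ellipticity values depend on unstated anchor and axis
  conventions and are explicitly not claimed.
* **Current sign:** records keep transfer = charge × direction while the
  reported current uses the electrode (cis→trans) convention; the two
  differ only by a sign and the choice keeps \eqn{G>0} for passive
  transport at either voltage polarity.
* **Screening rule** for conformer reports: flag conductance < 0.6 nS
  *or* anion/cation ratio < 4 (both thresholds configurable), a pure,
  idempotent filter.
* **Selectivity caveat:** with fewer than 5 minority-species events the
  ratio is flagged as overestimation-prone rather than suppressed.

## Problem sizes

The test-suite and reproduction-script runs use: 10⁶-step Langevin runs
(5 seeds, both biased and unbiased; the unbiased reference gets 4×10⁶
steps in the reproduction script because it mixes across the barrier an
order of magnitude more slowly than the boosted runs), 2000-frame peptide
ensembles of 25--60 residues, 4000-frame / 50-ion boxes, and 10⁶-cycle
GCMC/BD runs (2-ps steps for the wide-pore physics checks).  These sizes
were chosen so every stochastic tolerance sits several standard errors
from its bound under the generators' default conditions.

## Known limitations

Ideal-ion GCMC/BD (no screening, no saturation); no excluded volume or
side chains in peptide generators; torsion-window helix assignment rather
than hydrogen-bond-based secondary structure; straight-z pores only; the
toy sampler covers a closed set of analytic potentials.  The package
validates estimators and protocol structure — not force fields, and not
trajectory-dependent numbers of any specific channel system.

## A compact worked example

```{r example, eval = FALSE}
pot  <- toy_potential("double_well_1d", barrier = 2, tilt = 0.4)
bias <- boost_parameters(E_p = potential_energy(pot, 0) + 1, alpha_p = 2)
run  <- sample_langevin(pot, sampler_config(n_steps = 1e6, seed = 1,
                                            burn_in = 5e4), bias = bias)
w    <- maclaurin_weights(run$boosts, kT = kT_kcal(), k_max = 10)
well_free_energy_gap(run, weights = w)          # vs boltzmann_well_ratio(pot)
pmf  <- reweighted_pmf(run$positions[, 1], weights = w, bin_width = 0.25)
plot(pmf)
```
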