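---
title: "Regularized relative entropy minimization for coarse-grained binding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized relative entropy minimization for coarse-grained binding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bottom-up coarse-grained (CG) models are trained for thermodynamic
consistency with a finer (usually atomistic) reference ensemble. For
molecular complexes this runs into a sampling problem: reference
simulations almost always start from the bound structure and never
dissociate, so the training data carry no information about the true
binding affinity. Relative entropy minimization (REM) trained on such data
keeps deepening the inter-molecular interactions — the complex becomes ever
more stable with no lower bound, even after the structure is already
described well. regcg implements a regularized REM (reg-REM) that fixes
this by biasing the mean inter-molecular CG energy toward a target value
while leaving the structural training intact.

# The model

A CG system is a set of beads grouped into monomers. The potential is

U = U_bond + U_elec + U_rep + U_att

with all nonbonded sums running over inter-monomer pairs only, truncated at
a cutoff (default 2.5 nm):

* **U_bond** — harmonic intramonomer springs (a heteroelastic network),
  `0.5 k_IJ (R - r0)^2`, fitted by `henm_fit()`.
* **U_elec** — Debye-screened Coulomb,
  `ke Q_I Q_J / (eps_r R) exp(-kappa_D R)` with `ke = 138.935458
  kJ mol^-1 nm e^-2`; defaults `eps_r = 17.5`, `kappa_D = 1.274 nm^-1`
  (an implicit-solvent, 250 mM salt regime). Bead charges are sums of the
  mapped fine-particle charges.
* **U_rep** — a soft cosine repulsion `A_IJ H(R_rep - R)(1 + cos(pi
  R/R_rep))` plus a `B/R^4` core (default `B` = 6 kcal/mol A^4 =
  2.5104e-3 kJ mol^-1 nm^4) that keeps opposite-charge pairs bounded
  below. `A_IJ` is assigned from charge signs in multiples of 10 kcal/mol
  (`assign_A()`); `R_rep` from the distance distribution
  (`determine_R_rep()`: the largest radius below the first peak where the
  density is at most 5% of the peak). `H(0)` is taken as 1; the bracket
  vanishes there, so this is a determinism convention only.
* **U_att** — a Gaussian well `C_IJ/(sigma sqrt(2 pi)) exp(-(R -
  R_att)^2/(2 sigma^2))`, `sigma = 0.2 nm` globally, centred at the first
  peak of the reference distance distribution (or, in multimer mode, at
  the minimum mean inter-monomer type-pair distance). The signed
  amplitudes `C_IJ` (attraction = negative) are the trainable parameters
  theta.

Internal units are kJ/mol, nm, ps, K, u, e; in this system
`1 u nm^2 ps^-2 = 1 kJ/mol`. Inputs quoted in kcal are converted at 4.184
on read and the conversion is reported.

The open question whether the `B/R^4` core should apply to all pairs or
only opposite-sign pairs is resolved as: all pairs by default, with a
per-pair `b_term` flag to disable it. At the default `B` the term is
negligible (0.04 kJ/mol at 0.5 nm) except at near-contact distances, so
the choice does not affect training.

## Cutoff handling

Energies and forces are truncated sharply at the cutoff and the energy is
*not* shifted: the REM estimators average absolute energies, and a shift
would move every recorded `V_bind` by a state-independent constant. The
truncation discontinuity at 2.5 nm is ~1e-5 kJ/mol for the default well
parameters and irrelevant to sampling.

# Training

## REM

The loss is the Kullback-Leibler divergence from the mapped reference to
the CG ensemble (the mapping-degeneracy term is independent of theta and
dropped). Its gradient is the difference of ensemble-averaged parameter
gradients,

grad L = beta ( <dU/dtheta>_ref - <dU/dtheta>_CG ),

and parameters follow plain gradient descent `theta <- theta - gamma grad`.
For Gaussian amplitudes `dU/dC_IJ` is the theta-independent Gaussian
factor summed over in-range pairs, so the reference-side average is
computed once and cached — an exact optimization, not an approximation.

## reg-REM

The regularized loss adds `kappa (V0 - Vbar)^2`, where `Vbar` is the mean
inter-molecular CG energy (optionally of one designated monomer pair).
Its gradient uses the covariance (fluctuation) estimator

d<V>/dtheta = <dV/dtheta> - beta <V dU/dtheta> + beta <dU/dtheta><V>,

which only needs the per-frame binding energy and parameter gradients
already recorded during sampling. With `kappa_reg = 0` the reg-REM
gradient reduces to the plain REM gradient bitwise. When theta is purely
intermolecular and `V_bind` spans all inter-monomer pairs,
`dV/dtheta = dU/dtheta`; in multimer mode the designated-pair gradient is
computed separately while the full-system gradient enters the covariance.

## Choosing kappa

`kappa_heuristic()` balances a KL gradient of `0.5 beta nm^-1` against the
regularization gradient at a 1 kcal/mol binding-energy error:
`kappa = 0.25 beta / (<dV/dtheta> * 4.184)` in (kJ/mol)^-2. With the
typical gradient scale `<dV/dtheta> ~ 1 nm^-1` of Gaussian-amplitude
parametrizations this gives `kappa ~ 0.1/4.184` at 310 K, the default
used throughout.

## Learning rate, step cap and the converged model

Per-iteration gradients are estimated from finite Langevin runs and are
noisy; the binding mode of a small complex mixes slowly, so per-iteration
`Vbar` estimates fluctuate by several kJ/mol. Three choices keep the
descent stable:

* default `gamma = 1.5` (kJ/mol)^2 nm^2 with a per-iteration cap
  `max_step = 1 kJ mol^-1 nm` on the largest theta change — large enough
  to traverse the well-depth scale (a few kJ mol^-1 nm) in tens of
  iterations, small enough that the regularization feedback does not
  overshoot and oscillate;
* on a simulation blow-up the last update is redone at half step from the
  previous theta, once, before aborting;
* the *converged model* is the mean theta over the final window
  (`converged_params()`, default 20 iterations), analogous to picking a
  converged model among late iterations; the final single iterate is one
  noisy sample.

Each iteration restarts sampling from the native (bound) structure, so the
recorded per-iteration RMSD is an RMSD-to-native trace, and all recorded
frames enter the averages — including dissociated frames at weak targets,
whose fraction is logged per iteration (`frac_unbound`).

# Sampling

`simulate_cg()` integrates Langevin dynamics with the BAOAB splitting
(accurate configurational sampling at large steps), default 15 fs step and
1 ps^-1 friction (the thermostat strength is a free choice; it affects
kinetics, not sampled distributions). With zero friction or zero
temperature the scheme reduces to velocity Verlet, which the
energy-conservation checks exploit. Complexes are simulated in open
boundaries; an optional spherical reflecting wall about the origin bounds
the accessible volume so that dissociated monomers re-encounter each other
and rebinding is observable. The wall radius is a concentration-like
parameter: the defaults (1.1 nm for the compact dimer, 2.0-2.5 nm for the
chain pair and trimer) were chosen once so that unbind/rebind mixing is
fast relative to the per-iteration sampling length and dissociated
excursions stay short enough that trajectory-mean structural measures
remain informative. All pair interactions
are evaluated by direct summation within the cutoff — every system in
scope has well under 200 beads, so no neighbour list is used.

# Mapping and bonded fitting

`pca_subspace()` superposes frames onto their mean structure and
diagonalises the 3n x 3n coordinate covariance; by default the smallest
number of components capturing 90% of the variance is retained.
`edcg_residual()` evaluates the essential-dynamics residual chi^2 — the
mean squared difference of PC-subspace fluctuations summed over particle
pairs within each bead, normalised by 3 x (bead count) — in closed form
from the component variances (algebraically identical to the frame
average for projected fluctuations, because PC amplitudes are
uncorrelated). `edcg_partition()` minimises chi^2 over contiguous
segmentations by exact dynamic programming (O(n^2 B)); ties break toward
the lexicographically smallest boundary vector, and a seeded
boundary-annealing variant is available for very long chains.
Bead positions are mass-weighted means by default (uniform optional);
bead charges and masses are sums, so both are conserved exactly.

`henm_fit()` alternates sampling of the spring network with the compliance
update `1/k <- 1/k - gamma_hENM (<R^2>_CG - <R^2>_ref)`. The matched
`<R^2>` statistic is, by default, the *centred* second moment
`<R^2> - <R>^2` of each spring distance. The raw second moment is
dominated by the squared mean distance, and because rest lengths are set
from reference mean distances — which already contain the entropic
stretch of the reference model — a raw-moment fit has its fixed point at
systematically stiffened constants (3-6x in our recovery experiments); the
fluctuation is the quantity the elastic network is meant to reproduce,
and matching it recovers generating spring constants to a few percent.
A `statistic = "raw"` mode remains available. Springs connect
intramonomer bead pairs closer than `r_enm` (default 2 nm) in the
reference, with rest lengths at the reference mean distances and `k`
initialised at 500 kJ mol^-1 nm^-2, clamped to [1, 1e5]. Since
`d<R^2>/d(1/k)` is of order `kB T`, the default `gamma_hENM = 0.3 beta`
is a damped Newton step; each iteration additionally caps the relative
compliance change at 20%. Because springs are intramonomer and nonbonded
terms inter-monomer, the bonded fit is decoupled from the nonbonded model.

# Synthetic reference systems

The fixtures module generates the reference data for all tests: ensembles
sampled (with this package's own engine) from ground-truth CG models whose
parameters are shipped alongside, emulating the three binding regimes of
interest.

* `make_dimer_reference()` — a strongly bound dimer (default mean binding
  energy around -40 kJ/mol) of two rigid five-bead monomers. Each
  monomer is a compact "contact plate" (centre bead plus a ring of arms);
  the facing like-type Gaussian wells carry the trainable ground truth
  theta*, while orientational specificity comes from shape
  complementarity (wider soft-repulsion radii for unlike pairs) plus weak
  fixed cross attractions. Without these the binding wells are all
  parallel to the binding axis and rigid-body twist and slide are nearly
  free — an early design lesson reflected in the tests.
* `make_weak_duplex()` — two four-bead chains with one attraction rung per
  bead pair, terminal rungs at 60% strength: a weak-binding system
  (~ -16 to -19 kJ/mol at 300 K) that frays at the ends and shows
  unbind/rebind cycles at elevated temperature.
* `make_trimer_lattice()` — three identical monomers on a triangle sharing
  one type set and parameter table, for multimer-mode training on a
  designated pair (~ -55 kJ/mol per pair at theta*).
* `make_fine_chain()` — a bead-level chain sampled from known
  heterogeneous springs, each bead realised as a tight cluster of fine
  particles: the ground truth for mapping recovery (cluster boundaries)
  and hENM recovery (spring constants).

What the fixtures deliberately do *not* emulate: real protein or nucleic
acid geometry, sequence specificity, solvent degrees of freedom, or
atomistic force fields. Passing tests therefore demonstrate the
correctness and self-consistency of the estimators, the trainer and the
recovery machinery at desk scale — not the accuracy of any particular CG
model of a real system.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own study conditions: 10-12 bead systems, reference
ensembles of 2000-4000 frames (1e5-2e5 CG steps), training runs of 200
iterations at 50,000 steps per iteration, and final-window averages over
20 iterations. A full training run takes on the order of a minute on one
core.

Degenerate inputs are rejected rather than patched: overlapping beads
(zero pair distance) raise domain errors, diverging simulations abort with
the frame index, empty ensembles and invalid partitions are errors.
Quadrature oracles in the test suite use dense 1D grids with Boltzmann
frame weights — the `weights` field of the ensemble container exists
precisely so that deterministic "dense-sample" ensembles can stand in for
converged Monte Carlo sampling.

# Known limitations

* The CG potential is a potential of mean force; trained models are not
  temperature transferable, and the elevated-temperature duplex runs are
  qualitative demonstrations of unbind/rebind dynamics only.
* The binding mode of a small complex mixes slowly; per-iteration `Vbar`
  estimates carry several kJ/mol of noise, which is why converged models
  and reported binding energies are final-window averages.
* Only contiguous bead mappings are supported, and the bonded model is
  limited to harmonic pair springs (no angles or dihedrals).
* No periodic boundary conditions: box metadata is passed through but the
  engine is open-boundary with an optional spherical wall.
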