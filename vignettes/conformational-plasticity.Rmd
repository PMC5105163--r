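---
title: "Detecting rare conformational states of pMHCII: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rare conformational states of pMHCII: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmex)
```

# The scientific problem

Peptide-loaded MHC class II complexes (pMHCII) present antigens to CD4+
T cells.  Which peptide is presented depends on an exchange reaction
that can run spontaneously or be catalysed by HLA-DM, and the
susceptibility to catalysis is thought to be carried not by the ground
state — crystal structures of stable and exchange-prone complexes can
be nearly indistinguishable — but by rare excited conformations: a
partially unfolded β1-domain α-helix, an outward-flipped αW43 side
chain, a detached peptide terminus.  These states live at populations
of a few percent and below and interconvert on microsecond timescales,
so they are invisible to crystallography and direct NMR observation.
Two complementary windows remain:

* **Markov state models (MSMs)** built from large ensembles of MD
  trajectories, which resolve metastable states, their populations
  (hence free-energy differences) and interconversion rates;
* **NMR-detected hydrogen/deuterium exchange (HDX)**, which reports the
  equilibrium constant of transient local opening residue by residue.

`msmex` implements both quantitation chains plus the supporting
machinery (structural observables per metastable state, a bootstrapped
interaction-frequency statistic, the simulation restraint used to keep
the solute from tumbling in a tight periodic box), and a synthetic-data
generator that makes every stage testable against known ground truth.

# The Markov state model chain

## Featurization

The conformational changes of interest concentrate around the peptide
N-terminus, so the feature space is the set of pairwise Cα–Cα distances
over a residue selection — for the real system, the residues within
15 Å of βN82, which `select_within()` reproduces as a Cα-distance rule
with include/exclude overrides.  The published list (αH5–A10, αM23–D27,
αE30–F32, αF48–E55 without αR50, βR13–L27 without βN19, βR71–R93
without βR72 and βN82) contains 56 residues and hence 1540 distance
features.  The distance rule needed a decision: "residues within 15 Å"
is conventionally quoted without naming an atom, so the package uses
Cα–Cα distances and lets the override mechanism reproduce any exact
list.

## TICA

`fit_tica()` solves the generalized symmetric eigenproblem

$$\mathrm{sym}(C_\tau)\, v = \lambda\, (C_0 + \varepsilon I)\, v$$

with mean-free covariances accumulated over trajectories; lagged pairs
never cross a trajectory boundary.  Numerical choices:

* **Symmetrized `C_τ`** — guarantees a real spectrum for finite data;
  the plain estimator is asymmetric under sampling noise.
* **Ridge `ε = 1e-6 · trace(C_0)/d`** — pairwise distance sets are
  rank-deficient by construction (triangle constraints), so the
  whitening Cholesky needs regularization.  The default scales with the
  data; `reg = 0` reproduces the unregularized problem and fails loudly
  on singular input.
* **Sign convention** — the largest-magnitude loading of each component
  is forced positive, making projections reproducible across runs.
* **Three components** are kept by default, matching the number of slow
  coordinates the downstream three-state coarse-graining needs.
* The TICA lag is configurable and defaults to a small value (5 frames
  in the shipped examples); the MSM lag, not the TICA lag, controls the
  kinetic model, and slow eigenvalues are insensitive to the TICA lag
  on the synthetic data (the package tests check recovery of the latent
  relaxation time to 15%).

## Discretization shared across conditions

Conditions (wild type, point mutants) can only be compared
thermodynamically if their models live on the same microstates.
`kmeans_discretize()` therefore pools the reduced coordinates of all
conditions and fits one k-means center set (k-means++ seeding, Lloyd
iterations, fixed seed), then assigns every condition's frames to those
shared centers.  k = 100 microstates is the default operating point.

## Reversible maximum-likelihood estimation

`count_transitions()` uses sliding-window counts at the chosen lag
(every pair `(t, t+lag)`; windows never span trajectories).  Sliding
windows maximize data use; the correlation they introduce is absorbed
by the trajectory-level bootstrap rather than an effective-count
correction.  `largest_connected_set()` restricts to the largest
strongly connected component (ties broken by total counts, then by
smallest index).  `estimate_reversible_msm()` maximizes the likelihood
subject to detailed balance with the standard fixed-point iteration on
symmetric edge weights,

$$x_{ij} \leftarrow \frac{C_{ij} + C_{ji}}{c_i/x_i + c_j/x_j},$$

iterated until the stationary distribution moves by less than 1e-12.
The tests verify detailed balance to 1e-10 on every output and equality
with an independent BFGS likelihood maximizer to 1e-6 in `T` on random
small count matrices.

## Validation

Implied timescales `t_i(τ) = −τ/\ln λ_i(τ)` should be lag-invariant
where the model is Markovian; `implied_timescales()` recomputes the
model across a lag list.  `ck_test()` compares metastable set-to-set
self-transition probabilities predicted by `T(τ)^k` against models
re-estimated at lag `kτ`, with a trajectory-bootstrap 2σ band; lumping
a slow "trap" state with a fast-exiting one makes the test fail, which
the suite demonstrates.

## Coarse-graining and thermodynamics

`pcca()` implements PCCA+ memberships from the top `m` right
eigenvectors: simplex vertices chosen by successive orthogonalization,
memberships `χ = X A` with `A` the inverse of the vertex rows, tiny
negative entries clipped and rows renormalized.  A spectral gap below
1e-10 at the cut is refused (the decomposition would be arbitrary).
Populations use the crisp (argmax) assignment.  Free energies are
`ΔG_m = −RT \ln(Π_m/Π_{ref})` with the most populated state as
reference, R = 0.00831462 kJ/K/mol and T = 310 K by default — the
temperature of the underlying NMR experiments.

Cross-condition comparison matches metastable states by maximal Jaccard
overlap of their crisp microstate sets on the shared discretization
(best overlap below 0.2 is reported unmatched; exact ties are an
error), and converts population fold-changes to relative stabilizations
`ΔΔG = RT \ln(\mathrm{fold})` — the identity behind "28-fold ≈ 9 kJ/mol"
and "200-fold ≈ 14 kJ/mol" at 310 K.

Coarse rates are defined as `1/MFPT` with mean first-passage times from
the standard linear system on `T`, sources weighted by the stationary
distribution restricted to the source set.  This is a definition, not
an estimate of a specific relaxation eigenvalue; it is the quantity
kinetic network diagrams usually annotate.

## Uncertainty

`msm_bootstrap()` resamples entire trajectories with replacement while
holding the k-means centers and the microstate→metastable map fixed,
re-estimates counts and the reversible matrix per replicate, and
reports 15.87/84.13 percentiles as asymmetric 1σ bounds (populations
near 0 or 1 have skewed sampling distributions, so percentile bounds
are preferred over a symmetric ±sd).  Replicates in which a metastable
state vanishes are dropped and counted.  The suite includes a coverage
simulation: the 1σ interval contains the true population in roughly 68%
of independent repetitions.

# Per-state observables and the interaction statistic

`assign_frames()` labels every frame with the crisp metastable state of
its microstate (frames in pruned microstates stay unassigned and are
reported as such).  On top of the labels:

* `flip_probability()` — fraction of state-frames whose reporter
  dihedral falls in the flipped-out interval.  The interval is
  configuration, not inference: "flipped-out" is a structural notion
  with no standard numeric definition, so the package requires the
  user (or the synthetic archetypes) to declare it.
* `contact_frequency()` — minimum heavy-atom distance rule, 4.0 Å
  default, inclusive.  `solvent_contact_frequency()` uses solvent
  oxygens at 3.5 Å; without solvent atoms it switches to a flagged
  exposure-score proxy `1/(1+n_\mathrm{close})` and says so.  The
  cutoffs are conventional values, declared rather than fitted, and
  configurable.
* `helicity_profile()` — residue `i` is helical when
  `d(O_i, N_{i+4}) ≤ 3.5` Å, the α-helical H-bond geometry.  This is
  chosen over dihedral windows because it remains meaningful for the
  generator's pseudo-backbones; on an ideal helix built at
  φ = −57°, ψ = −47° the O···N(i+4) distance is 3.09 Å, on an extended
  chain 12.3 Å, so the classification is sharp.
* The Pairwise Interaction Analyser (`interaction_frequencies()`)
  implements the bootstrapped statistic: per replicate, entire
  trajectories are resampled, the MSM is re-estimated on the fixed
  discretization, 100 frames are drawn from the state's frames with
  probabilities proportional to the updated stationary weight of each
  frame's microstate (the consistent reading of "resample trajectories,
  fixed microstates, updated model"), and each pair's presence fraction
  is recorded; means and SDs are taken over 50 replicates.  H-bond
  criteria default to 3.5 Å donor–acceptor, 2.5 Å hydrogen–acceptor,
  120° D–H···A, the conventional values, because the exact parameter
  set of the original detection programs is not published; the contact
  criterion is the same 4.0 Å rule as above.  Significant differences
  between states use `|Δmean| > z·sqrt(sd_A² + sd_B²)` with z = 2.

# HDX in the EX2 limit

In the EX2 regime the observed exchange rate of an amide is
`k_obs = K_ex · k_int`, so `K_ex = k_obs/k_int`, the protection factor
is `P = K_ex⁻¹`, and the opening free energy is

$$\Delta G_\mathrm{op/cl} = -RT \ln K_\mathrm{ex},$$

positive for protected amides.  The sign convention (closed state
favored ⇒ positive ΔG) is declared explicitly because both orientations
appear in the HDX literature.

`fit_decay()` quantifies a signal-to-noise series `S/N(t)`:

1. **fast** — the mean of the first three points is within 3× the noise
   level: the amide exchanged within the ~35 min dead time; half-life
   reported as "< 15 min".  The first-points rule (rather than "all
   points below noise") is deliberately robust: with 90 acquisitions a
   truly flat noise series exceeds 3σ somewhere with probability ~0.2.
2. **stable** — total relative decay across the series below 5%:
   half-life reported as "> 4000 min".
3. **excluded** — grossly increasing signal (overlapping peaks,
   artefacts) or a failed fit.
4. otherwise **fitted** — least squares of `A·exp(−k_obs t)` with
   positive parameters and no baseline offset: a fully exchanged amide
   falls into the noise, which is exactly what the fast/stable
   classification absorbs.

Intrinsic rates come from an external per-position table
(sequence-context models are not reimplemented); `intrinsic_rate()`
averages the available values at positions i−1, i, i+1, the package's
reading of the "average with respect to the i±1 position" convention.

The recovery suite fits 100 noisy decays at SNR 50 across the two
decades `k ∈ [10⁻⁴, 10⁻²]` per minute — the window the 35-min/90-point
grid can actually resolve, bounded by the dead time on the fast side
and the 60-h horizon on the slow side — and requires mean relative
error below 5% at every rate.  The fitted estimator is efficient (its
spread matches the Cramér–Rao bound for this design), so the error
budget is information-limited, not implementation-limited.

Chemical shift perturbations combine as
`Δδ = sqrt(Δδ_H² + (0.14·Δδ_N)²)`; the nitrogen weight is the common
literature value and is configurable.

# The center-of-mass / inertia restraint

To simulate a solute aligned with its box (saving the solvent shell
that rotational tumbling would otherwise require), the restraint
penalizes COM drift and rotation away from the principal axes:

$$E_\mathrm{com} = k_\mathrm{com}\,|r_\mathrm{com}-r_\mathrm{ref}|^2,
\qquad
E_I = k_I\,(I_{xy}^2 + I_{xz}^2 + I_{yz}^2),$$

with `I_ab = −Σ_i w_i y_{ia} y_{ib}` over COM-centered coordinates.
Restraint implementations differ in prefactors and weighting, so two
conventions are declared: **no ½ prefactor** in either term, and
**unit weights** by default.  Unit weights make the off-diagonal elements carry Å² units,
which is the only reading dimensionally consistent with the published
force constant of 2 kcal mol⁻¹ Å⁻⁴; a mass-weighted mode is available.
Because the weighted centered coordinates sum to zero, the gradient has
the closed form `∂E/∂y_{ia} = −2k w_i Σ_{b≠a} I_{ab} y_{ib}`, verified
against central finite differences to 1e-6 on random configurations.

`min_periodic_separation()` monitors the minimum distance between the
molecule and its 26 periodic images in an orthorhombic box and checks
it against twice the electrostatic cutoff (18 Å at the 9 Å cutoff);
when the molecular extent exceeds a box length the non-positive face
gap is reported and the check fails.  `demo_rigid_body()` propagates a
toy rigid body with first-order overdamped Langevin dynamics — enough
to show that the restraints pin the off-diagonal inertia elements and
the COM while free dynamics let the orientation diffuse, without
pretending to be an MD engine.

# The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture:

* `chain_from_populations()` builds the jump matrix
  `T = (1−a) I + a·1π'` which has the requested stationary distribution
  exactly, satisfies detailed balance, and relaxes with the single
  timescale `−1/ln(1−a)` set to the requested exchange time.  Rare
  states at 1–2% are therefore plantable with analytic free energies.
  The price is a degenerate fast spectrum — irrelevant for estimator
  tests, which see the sampled realization.
* `default_archetypes()` assembles a ~200-atom pseudo-protein (receptor
  α and β chains, short peptide) whose states differ in the features
  the real system's states differ in: a β-chain helix segment that
  unfolds in the last state (built at ideal φ/ψ and re-built extended),
  a side-chain flip reporter dihedral (elongated arm, ±90° torsions, so
  positional noise maps to small dihedral noise and the state is read
  off with error well below 1%), and a peptide that shifts and partially
  dissociates.  A Cα-only variant keeps large-scale estimator tests
  cheap.
* `emit_structures()` adds first-order autoregressive Gaussian noise
  (stationary σ = 0.25 Å, lag-1 correlation `exp(−1/τ)` with τ = 2
  frames by default).  The AR(1) structure matters: with white noise
  TICA's fast modes are degenerate and the test would not exercise the
  eigenvalue ordering.
* `generate_hdx_table()` emits exponential decays with additive noise
  spanning the fast/fittable/stable regimes on the 35-min/90-point
  acquisition grid.

What the generator does **not** emulate: real force-field energetics,
solvent, the actual MHCII fold and its 1540-dimensional feature
geometry, experimental baseline drifts, or peak overlap in spectra.
Green tests therefore demonstrate that the estimators recover planted
truth under the stated noise models — the statistical correctness of
the chain — not that any particular biological conclusion is
reproduced at desk scale.  The headline MD-derived numbers of the real
system (19 → 10 kJ/mol state energies, ~1.6% populations, flip
probabilities of 0.063 → 0.16) come from hundreds of microseconds of
all-atom simulation and real spectra; at desk scale the package covers
them through parameter-recovery experiments at matched population
values and through the exact analytic identities (`ΔΔG = RT ln 28 =
8.59 ≈ 9 kJ/mol`, `RT ln 200 = 13.66 ≈ 14 kJ/mol`).

## Problem sizes used in the shipped experiments

The validation suite and the acceptance script run, per condition, 50
trajectories × 10⁴ frames (5 × 10⁵ frames) of the Cα-only archetype
system with populations (0.776, 0.208, 0.016) and a 100-frame exchange
time, through TICA (lag 5), k-means (k = 100), a reversible MSM
(lag 20) and PCCA+ (3 states) with a 50-replicate bootstrap.  These
sizes resolve the 1.6% state with a relative population error of a few
percent and run in minutes on one CPU; they are the package's chosen
validation operating point, and all of them scale up through the same
interfaces.

# Known limitations

* PCCA+ uses the vertex-initialized linear transform with clipping; the
  trace-maximizing refinement step is omitted.  For well-separated
  metastable spectra (the regime the method is meant for) the
  memberships are near-crisp and the refinement is a no-op.
* Coarse rates are 1/MFPT, which differs from eigenvalue-derived rates
  when metastability is weak.
* The reversible estimator treats the active set as fixed; uncertainty
  from connectivity changes appears only through dropped bootstrap
  replicates.
* XTC trajectories are not read (no installed reader); PDB and DCD are.
* The solvent-contact proxy without explicit solvent is a flagged
  exposure heuristic, not a hydration measure.
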