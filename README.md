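# msmex

Markov state model analysis of conformational plasticity in
peptide-loaded MHC class II complexes (pMHCII).

Stable pMHCII complexes are not static: they transiently sample rare,
exchange-competent conformations — a partially unfolded β1-domain
α-helix, an outward-flipped αW43 side chain, a loosened peptide
N-terminus — that determine whether antigen exchange proceeds
spontaneously or through the catalyst HLA-DM.  Detecting states
populated at the percent level and below in microsecond-scale molecular
dynamics ensembles, and corroborating them with NMR-detected
hydrogen/deuterium exchange, requires a specific statistical tool chain.
`msmex` packages that chain for structural bioinformaticians and
computational biophysicists:

* **Featurization and reduction** — pairwise Cα–Cα distances over a
  residue selection (e.g. all residues within 15 Å of the peptide
  P2-contacting βN82, with overrides to reproduce a published list), and
  time-lagged independent component analysis (TICA) solving
  `sym(C_τ) v = λ (C_0 + εI) v` for the slow collective coordinates.
* **Markov state models** — shared k-means discretization across
  simulation conditions (k-means++ seeding), reversible
  maximum-likelihood transition matrix `T` with stationary distribution
  `π` (detailed balance `π_i T_ij = π_j T_ji` to 1e-10), implied
  timescales `t_i = −τ/ln λ_i`, Chapman–Kolmogorov validation, PCCA+
  coarse-graining into metastable states, free energies
  `ΔG_m = −RT ln(Π_m/Π_ref)`, coarse rates `1/MFPT`, and trajectory-level
  bootstrap 1σ intervals (15.87/84.13 percentiles).
* **Cross-condition comparison** — metastable states of two conditions
  matched on the shared microstates; population fold-changes converted
  to relative stabilizations `ΔΔG = RT ln(fold)`.
* **Per-state observables** — side-chain flip probabilities from a
  reporter dihedral, heavy-atom contact and solvent-contact frequencies,
  helicity profiles, and the bootstrapped Pairwise Interaction Analyser
  (100-frame samples, 50 replicates, H-bond and distance criteria) with
  significance calls between states.
* **HDX in the EX2 limit** — first-order decay fits of HSQC
  signal-to-noise series, half-life classification (`t½ < 15 min` fast,
  `> 4000 min` stable), protection factors `P = k_int/k_obs`, opening
  free energies `ΔG_op/cl = −RT ln K_ex` (R = 0.00831462 kJ/K/mol,
  310 K), and chemical shift perturbations.
* **Simulation restraints** — the harmonic center-of-mass plus
  inertia-tensor off-diagonal restraint (`E = k_com|Δr_com|²`,
  `E = k_I (I_xy² + I_xz² + I_yz²)`) with analytic gradients, and the
  periodic-image distance monitor (minimum separation ≥ 2× the
  electrostatic cutoff).
* **Synthetic ground truth** — a hidden metastable Markov chain with
  user-set stationary populations (rare states at 1–2% includable by
  construction) driving structure-like archetypes with AR(1) positional
  noise, plus synthetic HDX decay tables, so every stage can be
  validated against known answers.

## Worked example

Plant three metastable states at populations (0.78, 0.20, 0.02) with a
50-frame exchange time, simulate 20 trajectories of 5000 frames, and run
the full pipeline:

```r
library(msmex)

chain <- chain_from_populations(c(0.78, 0.20, 0.02), exchange_frames = 50)
arch  <- default_archetypes(3, detail = "calpha")
syn   <- synth_ensemble(chain, arch, n_traj = 20, traj_frames = 5000, seed = 1)
sel   <- unique(arch$top$atoms[, c("chain", "resno")])
feats <- pairwise_ca_distances(syn$ens, sel)
pl    <- msm_pipeline(feats, tica_lag = 5, msm_lag = 10, k = 50,
                      n_meta = 3, seed = 2, n_boot = 50)
pl
#> msm_pipeline: 1 condition(s), 50 microstates
#>   synthetic: populations 0.0169, 0.197, 0.786

pl$conditions[[1]]$energies
#>   state population dG_kJ_mol
#> 1     1  0.0168530  9.903247
#> 2     2  0.1973708  3.561086
#> 3     3  0.7857762  0.000000

pl$conditions[[1]]$boot$summary[, c("state", "pop_lo", "pop_up")]
#>   state     pop_lo     pop_up
#> 1     1 0.01406387 0.02164463
#> 2     2 0.18822868 0.20497050
#> 3     3 0.77463685 0.79523356

ddg_from_fold(28, temperature_K = 310)
#> [1] 8.588864
```

The rare state planted at 2% is recovered at 1.7% with a 1σ interval of
[1.4%, 2.2%] and a free energy of 9.9 kJ/mol above the ground state —
the regime in which a 28-fold population shift between two conditions
corresponds to a relative stabilization of 8.6 ≈ 9 kJ/mol.

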