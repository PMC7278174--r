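---
title: "Supervised molecular dynamics at desk scale: model, scenarios and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised molecular dynamics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The protocol

Supervised molecular dynamics (SuMD) accelerates the *observation* of
ligand-binding events without biasing the dynamics. The simulation is cut
into short windows. Within each window the distance between the
mass-weighted centroids of the ligand and of the binding site is sampled at
evenly spaced times and fitted with an ordinary least-squares line
(`ols_slope()`, computed as `cov(t, d)/var(t)`). A strictly negative slope
accepts the window: its final coordinates and velocities seed the next one.
Anything else — including an exactly zero slope — rejects it: the window is
re-run from its starting coordinates with freshly drawn Maxwell-Boltzmann
velocities. Thirty consecutive rejections abandon the run as unbound. When
an accepted window ends with the centroid distance below 5 Å the supervisor
switches itself off; thirty short unsupervised check windows then probe the
putative complex, supervision resuming whenever a check ends back above the
threshold, and a final unsupervised production run closes the protocol.
Because rejected windows are discarded, the accepted trajectory is a
concatenation of unbiased segments; the cost of rejections is accounted
separately as *total simulated time*, which is the honest currency for
comparing against plain dynamics.

Classic atomistic applications of this protocol use 600 ps windows and a
25 ns production run. `sumdlite` keeps the identical state machine but
defaults to 10 ps windows and a 1000 ps production at its coarse-grained
scale (`supervision_config()`); every protocol constant — window length,
100 distance samples per window, the 30-failure cap, the 5 Å threshold, the
30 checks — is a visible, documented parameter.

Three readings of the protocol are ambiguous in the usual prose
descriptions; the package fixes them explicitly and keeps each
configurable:

* **Zero slope is a failure.** "Negative slope" is read strictly; the
  slope is computed from the covariance formula, which is exactly zero for
  an exactly constant series (a least-squares solver would return rounding
  noise of either sign).
* **The binding check uses the end-of-window distance** (`bind_check =
  "end"`), not any intra-window excursion; `"any"` is available.
* **Centroids are mass-weighted** (`centroid = "geometric"` available).
* **Velocity reassignment on retries is an explicit Maxwell-Boltzmann
  redraw** from the supervisor's own seeded stream. In atomistic practice
  the reassignment is implicit in the stochastic thermostat; making it
  explicit makes retries reproducible bit for bit (every replica seed is
  derived as `seed + replica`).
* **Re-entering supervision from the check phase resets the failure
  counter** — the counter measures *consecutive* failures of the current
  supervised stretch.

## The engine

The engine is a coarse-grained NVT Langevin integrator (BAOAB splitting)
over a 12-6 Lennard-Jones plus Coulomb force field with harmonic bonds and
harmonic positional restraints, minimum-image periodicity when a cubic box
is present, and plain truncation of both nonbonded terms at a 9 Å cutoff.
Units are Å, ps, amu, kcal/mol, elementary charges;
1 kcal/mol = 418.4 amu Å² ps⁻². All harmonic terms use the
½·k·Δ² convention, so a bead restrained with force constant *k* samples a
positional variance of exactly k_B·T/k per axis — the property the
thermostat tests check. Defaults: dt = 0.002 ps, 310 K, friction 1 ps⁻¹
(the "low damping" regime typical of production thermostats).

Deliberate simplifications, stated as such: electrostatics are truncated,
not Ewald-summed — with a handful of point charges at this scale the
truncation artefacts are negligible against k_BT; bonds are stiff harmonics
rather than rigid constraints, which the 2 fs step tolerates comfortably at
these masses; only NVT is offered, the staged-pressure equilibration of
atomistic work being mapped onto NVT stages with the same restraint
schedule (`run_staged_equilibration()`, `default_equilibration_schedule()`:
restrain everything → restrain the receptor → restrain the site → free, at
1 kcal mol⁻¹ Å⁻²). Minimisation is a displacement-capped steepest descent
(`relax_system()`), sufficient to remove bad contacts in systems this
small.

The engine config carries a relative dielectric, default **80**. The
scenarios' solvent beads are neutral, so all screening of the few real
charges must be implicit; the aqueous bulk value is the standard choice for
that situation. The pair-level `coulomb_energy()` keeps dielectric 1 so
that the bare Coulomb constant (332.0637 kcal Å mol⁻¹ e⁻²) is exposed
exactly.

Every stochastic component threads an explicit RNG token (`sim_state()`
captures one; `langevin_segment()` advances it), so identical inputs give
bit-identical trajectories on one platform — the determinism the test suite
asserts.

## The synthetic scenarios

`build_funnel_system()` generates the study system: a rigid spherical
receptor shell (radius 9 Å, bead spacing ≈ 3 Å) with a conical aperture
(40° half-angle) leading to a pocket lined by attractive beads on a 3.5 Å
sphere that opens toward the aperture. The three-bead ligand (65 amu per
bead, ≈ 195 amu total — the mass of a xanthine-sized small molecule; a
lighter ligand diffuses so fast at friction 1 ps⁻¹ that a 10 ps window
cannot resolve a distance trend) starts 35 Å from the receptor centroid
along the aperture axis, the placement used in the atomistic protocol this
emulates. Shell beads are nearly inert (ε = 0.05 kcal/mol) so the ligand
does not stick to the outside; pocket-lining beads carry the binding
affinity.

The pocket depth is not left to chance: after building the geometry the
generator minimises the rigid-translation ligand–receptor interaction
energy from the pocket centre and rescales all receptor epsilons so the
minimum equals −`pocket_depth` *exactly* (pair energies carry
√ε_receptor through Lorentz–Berthelot mixing, hence the squared scale
factor). The default depth of 8 kcal/mol (≈ 13 k_BT at 310 K) makes
binding effectively irreversible over the budgets used, so first-crossing
times are well defined.

Two variants emulate the qualitative physics that matters for selectivity
studies. `make_vestibule_variant()` spreads a chosen total charge (the
canonical scenario: +3 e) over the shell beads flanking the aperture,
emulating positively charged extracellular-loop residues; with the +1 e
terminal bead of the charged-ligand scenario and dielectric 80 this is a
2–3 k_BT barrier across the vestibule — enough to slow passage measurably,
not enough to forbid it, which is the observed phenomenology for charged
antagonists at receptors with charged loop residues. Cryptic sub-pocket
cups and `add_solvent()` beads support the hydration-map analyses.

The receptor is *frozen* by default (`default_funnel_engine_config()`):
binding kinetics are then ligand-dominated and the replica experiments fit
on a single CPU. This is the exact-rigid limit of the stiff-restraint
receptor; restrained and fully mobile modes exist and are what the
equilibration and thermostat tests exercise. What the toy does **not**
emulate: conformational gating, explicit hydration thermodynamics (solvent
beads are neutral LJ particles), and any atomistic geometry — so passing
tests demonstrate the protocol and analysis machinery, not any claim about
a real receptor.

## The analyses

`per_residue_interaction_energy()` decomposes the ligand–receptor nonbonded
energy per frame and receptor residue into electrostatic and
Lennard-Jones parts; by construction (and by test, to 10⁻⁶ kcal/mol) the
residue sums reproduce the total. `interaction_energy_landscape()` bins the
per-frame totals by centroid distance into half-open `[k·w, (k+1)·w)` bins
(mean, sd — zero for singleton bins — and count; empty bins omitted).
`rmsd_series()`/`rmsf()` use closed-form Kabsch superposition via SVD; RMSF
superposes to the mean structure and accepts a separate fit selection so a
rigid core can anchor the fit. `pocket_volume()` counts grid points inside
an inclusion sphere farther than probe + σ/2 from every receptor bead
(probe 1.4 Å, the classic water radius; bead radius σ/2 consistent with the
LJ parameterisation). `water_occupancy_map()` reports, per voxel, the
fraction of frames containing at least one solvent-bead centre after
superposing each frame onto the first frame's receptor; voxel membership is
half-open per axis so voxels partition space. `hotspots()` applies a
strict > 10% occupancy threshold, the conventional reporting level for
hydration maps. Apo hydration analyses merge replicas by frame
concatenation after superposition — occupancy is a per-frame average, so
merging is exact.

## Numerical choices and degenerate inputs

* Pair distances below 0.1 Å abort with the offending pair named; a
  non-finite coordinate or energy aborts with the offending time.
* `save_interval` must be a multiple of `dt`; window length divided by the
  distance-sample count must respect the same constraint (the defaults,
  10 ps / 100 samples / 0.002 ps, do).
* Frozen–frozen pair interactions are constants of the motion and are
  omitted from the integrator's reported energy terms; `compute_forces()`
  always evaluates the full potential.
* The instantaneous temperature divides by the mobile-bead count only.
* A ligand already inside the binding threshold is rejected up front; an
  empty selection, a zero-variance time vector, a single-frame RMSF, a
  solvent-free occupancy map and an inclusion sphere leaving the box are
  all explicit errors.
* `run_sumd()` adds one pragmatic extension to the protocol: an optional
  `time_budget` (used by `binding_time_experiment()`), after which a run
  reports `budget_exhausted` — the protocol itself does not otherwise
  guarantee termination when binding never completes.

## Problem sizes

The shipped experiments use 20 replicas per arm (the replica count of the
atomistic protocol this mirrors), a 2000 ps per-replica budget, 10 ps
windows, and a 5×10⁵-step thermostat check on a 50-bead restrained system —
sizes chosen so the whole pipeline, tests included, runs in minutes on one
CPU while keeping the comparisons statistically meaningful (a one-sided
Mann-Whitney test at n = 20 per arm resolves the supervised/unsupervised
median separation comfortably; censored replicas enter at the budget
value, which is conservative for that comparison).

## Known limitations

Truncated electrostatics make the vestibule barrier cutoff-dependent; the
slope criterion at 100 samples per window is noisy for windows in which the
ligand barely moves (visible as retry streaks near the shell); the binding
threshold (5 Å to the site-lining centroid) sits close to the pocket
geometry, so bound ligands oscillate around it and post-binding checks can
bounce back into supervised stretches — honest behaviour of the protocol,
visible in the window logs. None of these affect the protocol's bookkeeping
invariants, which are tested exactly.
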