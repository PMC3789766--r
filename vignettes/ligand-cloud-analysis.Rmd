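---
title: "Ensemble analysis of small-molecule binding to disordered peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analysis of small-molecule binding to disordered peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandcloud)
```

## The problem

Intrinsically disordered proteins (IDPs) have no stable tertiary fold;
they exist as broad conformational ensembles. Small molecules can
nevertheless bind them — not at a single rigid pocket, but at dispersed,
interconverting sites and orientations, a picture sometimes called a
"ligand cloud around a protein cloud". The motivating system for this
package is the disordered c-Myc bHLHZip segment 370–409 bound by the
inhibitor 10074-A4 (with segment 410–437 as a non-binding control), but
every stage is generic: the inputs are a multi-frame structure (one
coordinate set per stored snapshot), a per-atom parameter table, and a
chain-to-role (peptide/ligand) mapping.

The package implements the complete analysis chain for such ensembles:

1. **Binding detection by buried surface (ΔSASA).** For every frame and
   residue, ΔSASA = SASA of the residue computed over the peptide atoms
   alone (ligand deleted, coordinates unchanged) minus its SASA in the
   full complex. A residue is *bound* in a frame when ΔSASA exceeds
   10 Å²; maximal runs of bound frames are *binding events*; events
   shorter than 10 ns are discarded; the *binding-time percentage* is the
   fraction of frames inside retained events, and contiguous
   high-percentage residues are merged into ranked *sites*.
2. **Conformational clustering.** Kabsch superposition gives the minimal
   backbone RMSD between every frame pair; greedy neighbour-count (Daura
   / GROMOS) clustering at a 2.0 Å cutoff yields clusters, populations
   and representative frames; superposing every member onto its cluster
   representative and recording the ligand's centre of mass produces the
   *ligand cloud* per cluster.
3. **Interaction matrices.** Residue–residue contact probabilities
   (any-atom distance < 4.0 Å, evaluated for `j > i + 2`), hydrogen-bond
   occupancies, and time-averaged Lennard-Jones / Coulomb energy
   matrices, plus the same three series residue-by-residue against the
   ligand.
4. **Chain-dimension and secondary-structure statistics.** Radius of
   gyration distributions, the empirical coil scaling law
   `Rg = 2.02 Å · N^0.6` (18.5 Å at N = 40), and dihedral-window
   secondary-structure propensities.
5. **Free-energy bookkeeping.** `ΔG = ΔH − TΔS` with linear uncertainty
   propagation, block statistics at a 200 ps cadence, and record
   comparisons (ΔΔG, ΔΔH, ΔU, affinity ratio `exp(−ΔΔG/kT)`).

## Synthetic data with known ground truth

Published μs-scale observables for this system (mean Rg 10.3 ± 0.6 Å,
helix content 27.7 ± 11.1%, three binding sites spanning residues
372–408, residence times of hundreds of ns) come from tens of
microseconds of replica-exchange and explicit-solvent MD. No deposited
trajectories exist, and that scale is far beyond a test suite. The
package therefore ships two generators whose *ground truth is known by
construction*, and validates the machinery on them:

- `simulate_cg()` — a BAOAB Langevin integrator for a bead-spring
  peptide (one bead per residue; harmonic bonds at 3.8 Å, harmonic
  angles about 120°, WCA excluded volume) plus a ligand of 1–3 beads.
  Each ligand bead feels an attractive Lennard-Jones tail of
  per-residue depth ε_i (the *stickiness*), truncated and shifted at
  2.5σ and split WCA-style so the repulsive core (fixed 1 kcal/mol) is
  present even at ε_i = 0. A designed binding site is simply a run of
  residues with ε_site ≫ ε_background; `ground_truth_sites()` recovers
  it from the specification. The system lives in a cubic box (default
  80 Å) with reflecting walls, so every distance and surface analysis is
  image-free. Defaults (dt 0.01 ps, friction 1/ps, 300 K) were chosen
  for integrator stability, not physical fidelity.
- `sample_conformer_mixture()` — frames drawn from weighted rigid
  templates plus isotropic Gaussian noise, emulating a multi-basin
  ensemble with unequal basin weights; the true component labels are
  attached to the trajectory.

What the generators deliberately do *not* emulate: solvent, atomistic
side chains, force-field thermodynamics, and any quantitative
residence-time model. Passing tests therefore demonstrate that the
*measurement machinery* is correct (site recovery, population recovery,
invariances, exact bookkeeping), not that the coarse model reproduces
experimental ensembles.

Problem sizes used in the validation suite — chosen so the whole run
completes comfortably on a single CPU — are 12–40-residue chains,
2 × 10⁴ to 10⁶ integration steps (40 ps–10 ns of model time, frames
every 2 ps), and 400–1000-frame mixture ensembles. The longest run is
the site-recovery benchmark: a ligand starting at a random position in
an 80 Å box needs several nanoseconds just to find the chain, so
shorter runs measure diffusion-limited search rather than site
occupancy.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| ΔSASA binding threshold | 10 | Å² | strict `>`, per residue per frame |
| minimum event duration | 10 | ns | runs shorter than this are ignored |
| probe radius | 1.4 | Å | water-sized probe |
| sphere points | 256 | – | golden-spiral grid, deterministic |
| RMSD cluster cutoff | 2.0 | Å | backbone atoms (all beads when coarse-grained) |
| contact cutoff | 4.0 | Å | any-atom, `j > i + 2`, strict `<` |
| H-bond criterion | 3.5 Å, 30° | – | D···A distance, H–D···A angle |
| Coulomb constant | 332.0636 | kcal·Å/(mol·e²) | no distance cutoff |
| MM/PBSA cadence | 200 | ps | block length for block statistics |
| temperature | 300 | K | affinity ratios, simulation target |

The SASA numerics (probe, point count, radii set) are not prescribed by
any published protocol for this system; they are package defaults, and
the sensitivity of the 10 Å² threshold to them is left to the user to
explore — both are plain arguments.

## Numerical and design choices

- **Frame-local unbound reference.** ΔSASA uses the same frame with
  ligand atoms deleted, not a separate apo simulation. This is the only
  frame-local reading of "difference between bound and unbound SASA",
  and it makes ΔSASA ≥ 0 an exact identity (removing occluders can only
  expose surface), which the suite asserts on every synthetic run.
- **Strictness conventions.** Binding requires ΔSASA *strictly* above
  10 Å²; contacts require distance *strictly* below 4.0 Å; a single
  sub-threshold frame terminates a binding event (no gap tolerance —
  "continuous" read literally; the filter is configurable).
- **Percentage composition.** Binding percentages are computed from
  duration-*filtered* events by default; the unfiltered raw-mask order
  is available via `count_unfiltered = TRUE` in `binding_summary()`.
- **Daura tie-break.** When two frames have equal neighbour counts the
  lowest frame index wins; populations are fractions of *all* frames,
  so cluster sizes are non-increasing and deterministic.
- **Proper rotations only.** Kabsch superposition corrects the
  reflection branch of the SVD, so mirror images superpose with a
  proper rotation (det +1) and nonzero RMSD; collinear subsets raise a
  degeneracy error.
- **Linear uncertainty propagation.** ΔG sd = ΔH sd + TΔS sd (linear
  sum, not quadrature): this is the only rule that reproduces every
  printed uncertainty in the packaged MM/PBSA summary table
  (13.2 = 6.5 + 6.7, 14.7 = 6.9 + 7.8, 14.3 = 6.9 + 7.4,
  17.2 = 7.2 + 10). One row of that table prints −2.3 where
  ΔH − TΔS gives −2.4; the record is preserved verbatim (a
  `thermo_record` accepts an explicit ΔG precisely for this), and the
  discrepancy is documented rather than corrected.
- **Cumulative occupancies** round half-up to the nearest integer
  percent, matching the "about 77% versus 50%" convention for top-8
  cluster coverage.
- **Secondary structure without hydrogen-bond topology.** True
  DSSP/PROSS assignment needs atomistic H-bond patterns that
  coarse-grained beads cannot supply. Labels come instead from (φ,ψ)
  mesostate windows — H: φ∈[−100°,−30°], ψ∈[−80°,−5°];
  PPII: φ∈[−110°,−50°], ψ∈[120°,180°]; E: φ∈[−180°,−90°],
  ψ∈[90°,180°] excluding the PPII window; else coil — with helix
  requiring runs of ≥ 3 consecutive residues (echoing the minimal DSSP
  helix) and chain termini labelled coil. The windows are arguments, so
  users can recalibrate against a reference assigner on their own data.
  Coarse-grained chains use virtual dihedrals over bead quadruplets.
- **Coil scaling constants.** The coil law is fixed at 2.02 Å · N^0.6 —
  the standard denatured-state parameterisation, and the pair consistent
  with the 18.5 Å expectation at N = 40. Native-regime constants
  (2.2 Å, 0.38) are configurable and carry no printed check.
- **Site calling on designed synthetic contrasts.** A one-bead ligand
  diffusing along a wide designed site spreads its occupancy thinly
  (per-residue percentage ≈ bound fraction × contact width / site
  width — a few percent in the validation runs), while non-sticky
  residues never survive the threshold-plus-duration filter and sit at
  exactly 0%. Ground-truth recovery therefore calls sites as maximal
  runs of residues with *any* retained binding (`min_pct = 0.1`,
  `max_gap = 1`). On real atomistic data, where baseline noise is
  nonzero, a percentage cut of order 10–20% is the appropriate scale —
  which is why `min_pct` is a front-line argument rather than a
  constant.

## What the pipeline looks like

```{r, eval = FALSE}
eps <- rep(0.3, 40); eps[3:15] <- 3      # designed site, 10x contrast
cfg <- run_config(
  synthetic = list(chain = chain_spec(40, stickiness = eps),
                   ligand = ligand_spec(1),
                   params = simulation_params(n_steps = 5e5,
                                              save_interval = 200,
                                              seed = 7)),
  stages = c("binding", "clustering", "metrics"),
  min_duration_ns = 0.01, min_pct = 0.1)
report <- run_pipeline(cfg)
cat(render_report(report))
```

All stochastic behaviour flows through the config seeds: two runs with
an identical config produce byte-identical tables. Logs go to stderr;
stdout carries only the rendered summary (the thin command-line wrapper
in `inst/scripts/ligandcloud-cli.R` follows the same convention and
exits non-zero on any validation or stage failure).

## Known limitations

- The coarse-grained generator has no solvent, no side chains and no
  calibrated kinetics; residence times are qualitative (stickier sites
  bind longer), never quantitative.
- MM/PBSA ingestion is bookkeeping only: the Poisson–Boltzmann solver
  and entropy estimator that produce ΔH and TΔS are out of scope, so
  records come from tables (or gas-phase terms computed here, documented
  as partial).
- The SASA implementation is point-grid Shrake–Rupley, not an analytic
  power-diagram surface; accuracy is controlled by `n_sphere_points`
  (the suite checks 1% agreement against a dense Monte-Carlo surface
  oracle).
- Energy matrices use no cutoff and no periodicity, which is exact for
  the small, image-free systems analysed here but unsuitable for large
  periodic boxes.
- The PDB layer targets clean multi-model files (consistent MODEL
  blocks); altloc and insertion-code dialects are not supported.
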