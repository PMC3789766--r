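# ligandcloud

Analysis pipeline for molecular-dynamics ensembles of intrinsically
disordered proteins (IDPs) with small-molecule ligands. IDPs bind drugs
not at one rigid pocket but at dispersed, interconverting sites — a
"ligand cloud around a protein cloud". This package turns multi-frame
peptide+ligand structures into the quantities used to characterise such
binding, with the disordered c-Myc segment 370–409 and its inhibitor
10074-A4 as the reference system:

- **ΔSASA binding analysis** — Shrake–Rupley solvent accessible surface
  area; per-residue, per-frame ΔSASA (residue SASA with the ligand
  deleted minus SASA in the complex); binding events as maximal runs of
  frames with ΔSASA > 10 Å², discarding events shorter than 10 ns;
  binding-time percentages and ranked contiguous binding sites.
- **Conformational clustering** — Kabsch superposition, all-pairs
  backbone RMSD, Daura (GROMOS-style) greedy neighbour-count clustering
  at a 2.0 Å cutoff, cluster populations/representatives, and per-cluster
  **ligand clouds** (ligand centres of mass in the representative's
  frame).
- **Interaction matrices** — residue×residue contact probabilities
  (< 4.0 Å, `j > i + 2`), hydrogen-bond occupancies (3.5 Å / 30°),
  time-averaged Lennard-Jones and Coulomb energies
  (k_e = 332.0636 kcal·Å/(mol·e²), Lorentz–Berthelot), and per-residue
  peptide–ligand profiles.
- **Chain metrics** — radius-of-gyration distributions, the empirical
  coil scaling law Rg = 2.02 Å·N^0.6, and dihedral-window
  secondary-structure (helix / sheet / polyproline II / coil) content
  and per-residue helix propensity.
- **Free-energy bookkeeping** — ΔG = ΔH − TΔS with linear uncertainty
  propagation, 200 ps block statistics, and record comparisons
  (ΔΔG, ΔΔH, ΔU, affinity ratio exp(−ΔΔG/k_BT)).
- **Synthetic generators with known ground truth** — a coarse-grained
  BAOAB Langevin peptide+ligand simulator with designed per-residue
  ligand stickiness, and a weighted template-mixture conformer sampler;
  both are fully seeded and drive the validation suite.

See `vignettes/ligand-cloud-analysis.Rmd` for the model, assumptions and
design choices.

## Worked example

Enantiomer bookkeeping over the packaged MM/PBSA summary for 10074-A4
binding the c-Myc segments (all values in kcal/mol):

```r
library(ligandcloud)
recs <- read_thermo_table()
compare_thermo(recs[["c-Myc_370-409/S"]], recs[["c-Myc_370-409/R"]])
#> c-Myc_370-409/S vs c-Myc_370-409/R: ddG = -2.2, ddH = -3.2,
#> dU = -3.7 kcal/mol; affinity ratio 40.1 (T = 300 K)
```

The S form binds 2.2 kcal/mol more favourably than the R form — an
affinity ratio of about 40, so the racemate's activity is essentially
the S enantiomer's. The enthalpy gap (−3.2) tracks the gap in averaged
non-bonded potential (−3.7), as expected when binding is
interaction-driven.

Cluster-population arithmetic and the coil expectation:

```r
holo <- c(14.3, 13.9, 13.7, 10.4, 7.5, 6.9, 5.4, 5.2) / 100
cluster_population_report(holo, 8)$cumulative_pct
#> [1] 77
expected_rg(40, coil_law())
#> [1] 18.5
```

The top eight bound-state clusters cover 77% of the ensemble (the
unbound list gives 50%): ligand binding condenses the conformational
distribution without freezing it. A 40-residue random coil would be
expected at Rg = 18.5 Å.

End-to-end on a synthetic trajectory with a designed binding site
(residues 4–9 ten times stickier than background):

```r
eps <- rep(0.3, 15); eps[4:9] <- 3
cfg <- run_config(
  synthetic = list(chain = chain_spec(15, stickiness = eps),
                   ligand = ligand_spec(1),
                   params = simulation_params(n_steps = 3e4,
                                              save_interval = 200,
                                              seed = 29)),
  stages = c("binding", "clustering"),
  min_duration_ns = 0.002, min_pct = 10, sasa = sasa_params(1.4, 64))
report <- run_pipeline(cfg)
cat(render_report(report))
#> # ligandcloud analysis summary
#>
#> ## Binding sites (delta-SASA)
#>
#> - site 1: residues 4-9 (mean binding 23.8%)
#> ...
```

The top-ranked called site is exactly the designed one. (The event
duration filter is scaled to the nanosecond-length synthetic
trajectory; the 10 ns default applies to production-scale data.)

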