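Package: ligandcloud
Title: Ensemble Analysis of Small-Molecule Binding to Intrinsically
    Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics ensembles of
    intrinsically disordered peptides with small-molecule ligands:
    Shrake-Rupley solvent accessible surface area and per-residue
    delta-SASA binding-site detection with binding-event segmentation and
    binding-time percentages, Kabsch superposition with Daura (GROMOS)
    RMSD clustering, ligand-cloud summarisation, residue-residue and
    peptide-ligand interaction matrices (contacts, hydrogen bonds,
    Lennard-Jones, electrostatics), chain-dimension and dihedral-based
    secondary-structure statistics, and MM/PBSA-style free-energy
    bookkeeping. Includes a coarse-grained Langevin peptide+ligand
    simulator and a template-mixture conformer sampler that generate
    trajectories with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    withr,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
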