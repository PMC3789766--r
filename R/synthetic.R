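# Synthetic-data generators: a coarse-grained peptide+ligand Langevin
# simulator (one bead per residue) and a template-mixture conformer sampler.
# Both produce trajectories with known ground truth so every downstream
# stage can be validated against what was put in.

#' Specification of a coarse-grained peptide chain
#'
#' One bead per residue. `stickiness` sets the per-residue depth of the
#' attractive well between that residue's bead and the ligand, which is the
#' designed ground truth for binding-site recovery (a designed site carries
#' a larger well depth than the background).
#'
#' @param n_residues number of beads (>= 3).
#' @param bond_length equilibrium pseudo-bond length, Å (Cα-Cα spacing 3.8).
#' @param bond_k bond stiffness, kcal/mol/Å².
#' @param angle_k angle stiffness about 120 degrees, kcal/mol/rad².
#' @param excluded_volume_sigma WCA diameter for bead-bead repulsion, Å.
#' @param stickiness numeric of length `n_residues`, well depths in kcal/mol.
#' @param start_number first residue number (input numbering is preserved).
#' @param sequence optional one-letter sequence of length `n_residues` used
#'   for residue names.
#' @return object of class `chain_spec`.
#' @export
chain_spec <- function(n_residues, bond_length = 3.8, bond_k = 40,
                       angle_k = 2, excluded_volume_sigma = 4.5,
                       stickiness = rep(0, n_residues),
                       start_number = 1L, sequence = NULL) {
  if (n_residues < 3) stopf("n_residues must be >= 3")
  if (length(stickiness) != n_residues)
    stopf("stickiness must have one value per residue")
  if (any(c(bond_k, angle_k) < 0)) stopf("stiffnesses must be >= 0")
  if (!is.null(sequence) && nchar(sequence) != n_residues)
    stopf("sequence length must equal n_residues")
  structure(list(n_residues = as.integer(n_residues),
                 bond_length = bond_length, bond_k = bond_k,
                 angle_k = angle_k,
                 excluded_volume_sigma = excluded_volume_sigma,
                 stickiness = as.numeric(stickiness),
                 start_number = as.integer(start_number),
                 sequence = sequence),
            class = "chain_spec")
}

#' Specification of a coarse-grained ligand
#'
#' @param n_beads 1-3 beads; multi-bead ligands are held together by stiff
#'   bonds (a near-rigid rod when `rigid = TRUE`).
#' @param bead_radius bead radius, Å.
#' @param rigid use very stiff internal bonds.
#' @return object of class `ligand_spec`.
#' @export
ligand_spec <- function(n_beads = 1, bead_radius = 2.5, rigid = TRUE) {
  if (n_beads < 1) stopf("n_beads must be >= 1")
  structure(list(n_beads = as.integer(n_beads), bead_radius = bead_radius,
                 rigid = isTRUE(rigid)),
            class = "ligand_spec")
}

#' Langevin simulation parameters
#'
#' Defaults (0.01 ps step, 1/ps friction, 300 K) are chosen for integrator
#' stability of the bead-spring model, not for physical fidelity.
#'
#' @param temperature K (> 0).
#' @param friction collision rate, 1/ps.
#' @param dt time step, ps (> 0).
#' @param n_steps number of integration steps.
#' @param save_interval save a frame every this many steps (>= 1).
#' @param seed integer seed controlling all randomness of the run.
#' @param box_size reflecting-wall cubic box edge, Å.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(temperature = 300, friction = 1, dt = 0.01,
                              n_steps = 1e5, save_interval = 100,
                              seed = 1, box_size = 80) {
  if (dt <= 0) stopf("dt must be positive")
  if (temperature <= 0) stopf("temperature must be positive")
  if (save_interval < 1) stopf("save_interval must be >= 1")
  structure(list(temperature = temperature, friction = friction, dt = dt,
                 n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed), box_size = box_size),
            class = "simulation_params")
}

.aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

cg_topology <- function(chain, ligand = NULL) {
  resname <- if (is.null(chain$sequence)) rep("GLY", chain$n_residues) else
    unname(.aa3[strsplit(toupper(chain$sequence), "")[[1]]])
  top <- topology(
    atom_name = rep("CA", chain$n_residues),
    residue_index = chain$start_number + seq_len(chain$n_residues) - 1L,
    residue_name = resname,
    role = "peptide",
    radius = chain$excluded_volume_sigma / 2,
    charge = 0, lj_epsilon = 0.1, lj_sigma = chain$excluded_volume_sigma,
    mass = 110
  )
  if (!is.null(ligand) && ligand$n_beads >= 1) {
    ltop <- topology(
      atom_name = paste0("L", seq_len(ligand$n_beads)),
      residue_index = max(top$residue_index) + 1L,
      residue_name = "LIG", role = "ligand",
      radius = ligand$bead_radius, charge = 0, lj_epsilon = 0.1,
      lj_sigma = 2 * ligand$bead_radius, mass = 100
    )
    top <- rbind(top, ltop)
  }
  top
}

# Overlap-free initial conformation: beads on a gentle helix around the box
# centre (pitch/radius chosen so that all non-bonded distances clear the WCA
# core), which then relaxes under the thermostat.
init_chain_coords <- function(chain, box) {
  n <- chain$n_residues
  rise <- min(1.8, (box - 10) / max(n - 1, 1))
  omega <- 1.0
  r2 <- (chain$bond_length^2 - rise^2) / (4 * sin(omega / 2)^2)
  if (r2 <= 0) stopf("box too small for the chain length")
  R <- sqrt(r2)
  i <- seq_len(n) - 1
  z0 <- box / 2 - rise * (n - 1) / 2
  cbind(box / 2 + R * cos(omega * i),
        box / 2 + R * sin(omega * i),
        z0 + rise * i)
}

# random ligand placement clear of the chain
init_ligand_coords <- function(chain_xy, n_beads, spacing, box,
                               min_dist = 8) {
  for (try in 1:200) {
    base <- stats::runif(3, 0.2 * box, 0.8 * box)
    pos <- t(vapply(seq_len(n_beads) - 1L,
                    function(k) base + c(k * spacing, 0, 0), numeric(3)))
    d <- sqrt(outer(rowSums(pos^2), rowSums(chain_xy^2), "+") -
                2 * pos %*% t(chain_xy))
    if (min(d) > min_dist && all(pos > 2) && all(pos < box - 2))
      return(pos)
  }
  stopf("could not place ligand clear of the chain")
}

#' Simulate a coarse-grained peptide+ligand trajectory
#'
#' BAOAB Langevin integration of a bead-spring chain (harmonic bonds and
#' angles, WCA excluded volume between all non-bonded bead pairs) plus a
#' ligand whose beads feel, in addition to the WCA core, an attractive
#' Lennard-Jones tail of per-residue depth `chain$stickiness[i]`, truncated
#' and shifted at 2.5 sigma. The system lives in a cubic box with
#' reflecting walls so all downstream distance/SASA analyses are image-free.
#' Runs are fully reproducible from `params$seed`.
#'
#' @param chain a [chain_spec()].
#' @param ligand a [ligand_spec()] or `NULL` for an apo run.
#' @param params a [simulation_params()].
#' @return a [trajectory()]; per-frame instantaneous temperatures are
#'   attached as `attr(, "temperature")`.
#' @export
simulate_cg <- function(chain, ligand = NULL, params = simulation_params()) {
  top <- cg_topology(chain, ligand)
  nlig <- sum(top$role == "ligand")
  sigma_pl <- (chain$excluded_volume_sigma +
                 2 * (if (nlig) ligand$bead_radius else 1)) / 2
  withr::with_seed(params$seed, {
    x0 <- init_chain_coords(chain, params$box_size)
    if (nlig) {
      lx <- init_ligand_coords(x0, nlig, 2 * ligand$bead_radius,
                               params$box_size)
      x0 <- rbind(x0, lx)
    }
    res <- .cg_langevin_cpp(
      coords0 = x0,
      is_ligand = top$role == "ligand",
      mass = top$mass,
      eps_attr_bead = c(chain$stickiness, rep(0, nlig)),
      bond_length = chain$bond_length, bond_k = chain$bond_k,
      angle_theta0 = 120 * pi / 180, angle_k = chain$angle_k,
      sigma_pp = chain$excluded_volume_sigma,
      sigma_pl = sigma_pl,
      sigma_ll = if (nlig) 2 * ligand$bead_radius else 1,
      lig_bond_length = if (nlig) 2 * ligand$bead_radius else 1,
      lig_bond_k = if (nlig && ligand$rigid) 200 else 50,
      temperature = params$temperature, friction = params$friction,
      dt = params$dt, n_steps = params$n_steps,
      save_interval = params$save_interval, box = params$box_size
    )
  })
  traj <- trajectory(top, res$coords,
                     time_spacing = params$save_interval * params$dt)
  attr(traj, "temperature") <- res$temperature
  traj
}

#' Ground-truth binding-site residues of a chain specification
#'
#' @param chain a [chain_spec()].
#' @param threshold kcal/mol; residues with stickiness >= threshold.
#' @return integer residue numbers (in the chain's input numbering).
#' @export
ground_truth_sites <- function(chain, threshold) {
  idx <- which(chain$stickiness >= threshold)
  chain$start_number + idx - 1L
}

#' Specification of a template-mixture conformer ensemble
#'
#' Emulates a multi-basin conformational ensemble with unequal basin
#' weights: each frame is one of the `templates` drawn by `weights` plus
#' isotropic Gaussian coordinate noise.
#'
#' @param templates list of `n_atoms x 3` matrices (same atom count).
#' @param weights non-negative, summing to 1.
#' @param noise_sigma Gaussian displacement width, Å.
#' @param seed integer seed.
#' @return object of class `conformer_mixture_spec`.
#' @export
conformer_mixture_spec <- function(templates, weights, noise_sigma = 0.5,
                                   seed = 1) {
  if (!length(templates)) stopf("at least one template required")
  na <- vapply(templates, nrow, 0L)
  if (length(unique(na)) != 1) stopf("all templates must share an atom count")
  if (length(weights) != length(templates))
    stopf("one weight per template required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stopf("weights must be >= 0 and sum to 1")
  structure(list(templates = templates, weights = as.numeric(weights),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "conformer_mixture_spec")
}

#' Sample a trajectory from a conformer mixture
#'
#' @param spec a [conformer_mixture_spec()].
#' @param n_frames number of frames (> 0).
#' @param topology optional topology; defaults to a CA-bead chain matching
#'   the template atom count.
#' @param time_spacing ps between frames.
#' @return a [trajectory()]; the true template index of each frame is
#'   attached as `attr(, "components")`.
#' @export
sample_conformer_mixture <- function(spec, n_frames, topology = NULL,
                                     time_spacing = 20) {
  if (n_frames < 1) stopf("n_frames must be >= 1")
  na <- nrow(spec$templates[[1]])
  if (is.null(topology))
    topology <- cg_topology(chain_spec(max(na, 3)))[seq_len(na), ]
  coords <- array(NA_real_, dim = c(na, 3, n_frames))
  comp <- withr::with_seed(spec$seed, {
    comp <- sample.int(length(spec$templates), n_frames, replace = TRUE,
                       prob = spec$weights)
    for (f in seq_len(n_frames)) {
      coords[, , f] <- spec$templates[[comp[f]]] +
        matrix(stats::rnorm(3 * na, sd = spec$noise_sigma), na, 3)
    }
    comp
  })
  traj <- trajectory(topology, coords, time_spacing = time_spacing)
  attr(traj, "components") <- comp
  traj
}

#' Build an idealised peptide backbone from dihedral angles
#'
#' Constructs N/CA/C backbone coordinates for a chain with the given
#' phi/psi angles (degrees) using standard bond lengths and angles and
#' trans peptide bonds. Useful for helical/extended/polyproline-II test
#' templates.
#'
#' @param phi,psi numeric vectors of equal length `n_residues` (the first
#'   phi and last psi are ignored, as in a real chain).
#' @return topology + coords list: `$topology` (N/CA/C atoms per residue)
#'   and `$coords` (`3*n x 3` matrix).
#' @export
build_peptide_backbone <- function(phi, psi) {
  n <- length(phi)
  if (length(psi) != n) stopf("phi and psi must have equal length")
  b <- c(NCA = 1.458, CAC = 1.525, CN = 1.329)
  ang <- c(NCAC = 111.2, CACN = 116.2, CNCA = 121.7) * pi / 180
  place <- function(a, bq, cq, bond, theta, chi) {
    # extend from c along geometry defined by points a-b-c;
    # chi is the a-b-c-d dihedral with the standard sign convention
    chi <- -chi
    bc <- cq - bq; bc <- bc / sqrt(sum(bc^2))
    ab <- bq - a
    nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
             ab[3] * bc[1] - ab[1] * bc[3],
             ab[1] * bc[2] - ab[2] * bc[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
           nrm[3] * bc[1] - nrm[1] * bc[3],
           nrm[1] * bc[2] - nrm[2] * bc[1])
    d <- c(-bond * cos(theta), bond * sin(theta) * cos(chi),
           bond * sin(theta) * sin(chi))
    cq + d[1] * bc + d[2] * m + d[3] * nrm
  }
  xyz <- matrix(NA_real_, 3 * n, 3)
  xyz[1, ] <- c(0, 0, 0)                                   # N1
  xyz[2, ] <- c(b["NCA"], 0, 0)                            # CA1
  xyz[3, ] <- xyz[2, ] + b["CAC"] *
    c(cos(pi - ang["NCAC"]), sin(pi - ang["NCAC"]), 0)     # C1 via N-CA-C
  for (i in seq_len(n)) {
    iN <- 3 * (i - 1) + 1; iCA <- iN + 1; iC <- iN + 2
    if (i > 1) {
      pN <- iN - 3; pCA <- iCA - 3; pC <- iC - 3
      xyz[iN, ] <- place(xyz[pN, ], xyz[pCA, ], xyz[pC, ],
                         b["CN"], ang["CACN"], psi[i - 1] * pi / 180)
      xyz[iCA, ] <- place(xyz[pCA, ], xyz[pC, ], xyz[iN, ],
                          b["NCA"], ang["CNCA"], pi)        # omega 180
      xyz[iC, ] <- place(xyz[pC, ], xyz[iN, ], xyz[iCA, ],
                         b["CAC"], ang["NCAC"], phi[i] * pi / 180)
    }
  }
  top <- topology(
    atom_name = rep(c("N", "CA", "C"), n),
    residue_index = rep(seq_len(n), each = 3),
    residue_name = "GLY", role = "peptide",
    radius = rep(c(1.55, 1.7, 1.7), n), charge = 0,
    lj_epsilon = 0.1, lj_sigma = 3.2,
    mass = rep(c(14.007, 12.011, 12.011), n)
  )
  list(topology = top, coords = xyz)
}
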