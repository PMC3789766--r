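#' Build a topology table of atom records
#'
#' A topology is a `data.frame` with one row per particle (atom or
#' coarse-grained bead) carrying everything the energy and surface-area
#' stages need: residue assignment, a peptide/ligand role, van der Waals
#' radius, partial charge, Lennard-Jones parameters and mass.
#'
#' @param atom_name character, short atom/bead names (e.g. `"CA"`).
#' @param residue_index integer, 1-based residue numbers (input numbering is
#'   preserved throughout, e.g. 370..409).
#' @param residue_name character, residue codes.
#' @param role character, each `"peptide"` or `"ligand"`.
#' @param radius numeric, van der Waals radii in Å (> 0).
#' @param charge numeric, partial charges in elementary units.
#' @param lj_epsilon,lj_sigma numeric, Lennard-Jones well depth in kcal/mol
#'   (non-negative) and diameter in Å (positive).
#' @param mass numeric, masses in amu (> 0).
#' @return validated topology `data.frame`.
#' @export
topology <- function(atom_name, residue_index, residue_name, role,
                     radius, charge = 0, lj_epsilon = 0, lj_sigma = 1,
                     mass = 1) {
  top <- data.frame(
    atom_name = as.character(atom_name),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    role = as.character(role),
    radius = as.numeric(radius),
    charge = as.numeric(charge),
    lj_epsilon = as.numeric(lj_epsilon),
    lj_sigma = as.numeric(lj_sigma),
    mass = as.numeric(mass),
    stringsAsFactors = FALSE
  )
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  req <- c("atom_name", "residue_index", "residue_name", "role", "radius",
           "charge", "lj_epsilon", "lj_sigma", "mass")
  miss <- setdiff(req, names(top))
  if (length(miss))
    stopf("topology missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(top$role %in% c("peptide", "ligand")))
    stopf("topology role must be 'peptide' or 'ligand'")
  if (any(!is.finite(top$radius)) || any(top$radius <= 0))
    stopf("topology radii must be positive")
  if (any(!is.finite(top$mass)) || any(top$mass <= 0))
    stopf("topology masses must be positive")
  if (any(!is.finite(top$lj_sigma)) || any(top$lj_sigma <= 0))
    stopf("topology lj_sigma must be positive")
  if (any(!is.finite(top$lj_epsilon)) || any(top$lj_epsilon < 0))
    stopf("topology lj_epsilon must be non-negative")
  invisible(top)
}

#' Construct a trajectory
#'
#' A `trajectory` couples a topology with an ordered stack of coordinate
#' frames at uniform time spacing (the storage cadence of the underlying
#' simulation, e.g. one snapshot every 20 ps).
#'
#' @param topology topology `data.frame` (see [topology()]).
#' @param coords numeric array `n_atoms x 3 x n_frames` (Å), or a list of
#'   `n_atoms x 3` matrices.
#' @param time_spacing frame spacing in ps (> 0).
#' @param start_time time of the first frame in ps.
#' @return object of class `trajectory` with elements `topology`, `coords`
#'   (array), `times` and `time_spacing`.
#' @export
trajectory <- function(topology, coords, time_spacing = 1, start_time = time_spacing) {
  validate_topology(topology)
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, length(coords)))
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stopf("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[3] < 1) stopf("trajectory must contain at least one frame")
  if (dim(coords)[1] != nrow(topology))
    stopf("coordinate count (%d) does not match topology atom count (%d)",
          dim(coords)[1], nrow(topology))
  if (any(!is.finite(coords))) stopf("all coordinates must be finite")
  if (!is.finite(time_spacing) || time_spacing <= 0)
    stopf("time_spacing must be positive")
  structure(
    list(topology = topology, coords = coords,
         times = start_time + (seq_len(dim(coords)[3]) - 1) * time_spacing,
         time_spacing = time_spacing),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d atoms (%d peptide, %d ligand), %d frames @ %g ps\n",
    n_atoms(x), length(peptide_atoms(x)), length(ligand_atoms(x)),
    n_frames(x), x$time_spacing))
  invisible(x)
}

#' Trajectory accessors
#'
#' @param traj a `trajectory`.
#' @param i frame index.
#' @return `n_frames()`/`n_atoms()`: counts; `frame_coords()`: an
#'   `n_atoms x 3` matrix; `peptide_atoms()`/`ligand_atoms()`: integer atom
#'   indices; `peptide_residues()`: sorted unique residue numbers of the
#'   peptide chain.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[, , i, drop = FALSE]
  dim(m) <- dim(traj$coords)[1:2]
  m
}

#' @rdname n_frames
#' @export
peptide_atoms <- function(traj) which(traj$topology$role == "peptide")

#' @rdname n_frames
#' @export
ligand_atoms <- function(traj) which(traj$topology$role == "ligand")

#' @rdname n_frames
#' @export
peptide_residues <- function(traj) {
  sort(unique(traj$topology$residue_index[traj$topology$role == "peptide"]))
}

#' Default atom subset for backbone-RMSD analyses
#'
#' For atomistic input the backbone is taken as peptide atoms named
#' N/CA/C/O; coarse-grained input (no such names beyond CA beads) uses all
#' peptide beads.
#'
#' @param traj a `trajectory`.
#' @return integer atom indices.
#' @export
backbone_atoms <- function(traj) {
  pep <- peptide_atoms(traj)
  bb <- pep[traj$topology$atom_name[pep] %in% c("N", "CA", "C", "O")]
  if (length(bb) >= 3) bb else pep
}

#' Apply a rigid transform to every frame
#'
#' @param traj a `trajectory`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @return transformed `trajectory`.
#' @export
transform_trajectory <- function(traj, rotation = diag(3), translation = c(0, 0, 0)) {
  out <- traj
  for (f in seq_len(n_frames(traj))) {
    out$coords[, , f] <- frame_coords(traj, f) %*% t(rotation) +
      matrix(translation, n_atoms(traj), 3, byrow = TRUE)
  }
  out
}
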