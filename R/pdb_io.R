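# Multi-model PDB I/O. Parsing/formatting is delegated to bio3d; this layer
# adds per-model consistency validation, the chain->role mapping, and the
# topology defaults (per-element radii and masses) downstream stages need.

.element_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                     P = 1.80)
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

.guess_element <- function(atom_name) {
  el <- toupper(substr(gsub("^[0-9]", "", atom_name), 1, 1))
  ifelse(el %in% names(.element_radius), el, "C")
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame. Chains are mapped to the
#' peptide/ligand role through `chain_roles`; every chain present in the
#' file must be mapped. Atom radii and masses are assigned from a per-element
#' table (H/C/N/O/S/P; unknown elements fall back to carbon); charges and
#' Lennard-Jones parameters default to zero/one and can be replaced with
#' [attach_topology()].
#'
#' @param path PDB file path.
#' @param chain_roles named character vector mapping chain id to role, e.g.
#'   `c(A = "peptide", B = "ligand")`.
#' @param time_spacing frame spacing in ps assigned to the models.
#' @return a [trajectory()].
#' @export
read_pdb_models <- function(path, chain_roles, time_spacing = 20) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    model_id <- findInterval(which(is_atom), model_starts)
    counts <- table(model_id)
    if (length(unique(counts)) > 1) {
      ref <- as.integer(counts[1])
      bad <- names(counts)[which(as.integer(counts) != ref)[1]]
      stopf("inconsistent atom count in MODEL %s (%d atoms, expected %d)",
            trimws(substr(lines[model_starts[as.integer(bad)]], 7, 20)),
            as.integer(counts[bad]), ref)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain)
  chains[is.na(chains)] <- " "
  unknown <- setdiff(chains, names(chain_roles))
  if (length(unknown))
    stopf("chain(s) %s not present in chain_roles mapping",
          paste(unknown, collapse = ", "))
  role <- unname(chain_roles[ifelse(is.na(at$chain), " ", at$chain)])
  if (!all(role %in% c("peptide", "ligand")))
    stopf("chain_roles values must be 'peptide' or 'ligand'")
  el <- .guess_element(at$elety)
  top <- topology(
    atom_name = at$elety, residue_index = at$resno,
    residue_name = at$resid, role = role,
    radius = unname(.element_radius[el]), charge = 0,
    lj_epsilon = 0, lj_sigma = 1, mass = unname(.element_mass[el])
  )
  nf <- nrow(pdb$xyz)
  coords <- array(NA_real_, dim = c(nrow(top), 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(top, coords, time_spacing = time_spacing)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Standard fixed-width records, coordinates at 3 decimals, one
#' `MODEL`/`ENDMDL` pair per frame; ligand atoms are written as `HETATM`.
#' Residue numbering is preserved from the topology.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(traj, path) {
  if (any(abs(traj$coords) >= 10000))
    stopf("coordinate magnitude exceeds the 8.3 PDB field width")
  top <- traj$topology
  rec <- ifelse(top$role == "ligand", "HETATM", "ATOM  ")
  chain <- ifelse(top$role == "ligand", "B", "A")
  # atom names shorter than 4 characters start in column 14
  nm <- ifelse(nchar(top$atom_name) < 4,
               sprintf(" %-3s", top$atom_name),
               sprintf("%-4s", substr(top$atom_name, 1, 4)))
  el <- .guess_element(top$atom_name)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, seq_len(nrow(top)), nm, substr(top$residue_name, 1, 3), chain,
      top$residue_index, m[, 1], m[, 2], m[, 3], 1, 0, el), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a topology parameter table
#'
#' Tab-separated text with a one-line header and the columns `atom_name`,
#' `residue_index`, `residue_name`, `role`, `radius`, `charge`,
#' `lj_epsilon`, `lj_sigma`, `mass`. Numeric fields accept both the ASCII
#' hyphen-minus and the typographic minus sign found in typeset tables.
#'
#' @param path file path.
#' @return topology `data.frame` in file order.
#' @export
read_topology <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
  req <- c("atom_name", "residue_index", "residue_name", "role", "radius",
           "charge", "lj_epsilon", "lj_sigma", "mass")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stopf("topology file missing column(s): %s", paste(miss, collapse = ", "))
  num_cols <- c("residue_index", "radius", "charge", "lj_epsilon",
                "lj_sigma", "mass")
  for (cn in num_cols) {
    parsed <- parse_numeric(raw[[cn]])
    bad <- which(is.na(parsed) & !is.na(raw[[cn]]))
    if (length(bad))
      stopf("non-numeric value '%s' in column '%s' at line %d",
            raw[[cn]][bad[1]], cn, bad[1] + 1L)
    raw[[cn]] <- parsed
  }
  topology(raw$atom_name, raw$residue_index, raw$residue_name, raw$role,
           raw$radius, raw$charge, raw$lj_epsilon, raw$lj_sigma, raw$mass)
}

#' Write a topology parameter table
#'
#' @param top topology `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  validate_topology(top)
  write.table(top, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Replace a trajectory's topology with one read from a parameter table
#'
#' @param traj a [trajectory()].
#' @param top topology `data.frame`, e.g. from [read_topology()]; must match
#'   the trajectory atom count and order (checked on names and residues).
#' @return the trajectory with `top` attached.
#' @export
attach_topology <- function(traj, top) {
  validate_topology(top)
  if (nrow(top) != n_atoms(traj))
    stopf("topology has %d atoms but trajectory has %d",
          nrow(top), n_atoms(traj))
  if (!all(top$residue_index == traj$topology$residue_index))
    stopf("topology residue numbering does not match the trajectory")
  traj$topology <- top
  traj
}
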