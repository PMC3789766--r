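# Residue-residue and peptide-ligand interaction analyses: contact
# probabilities, Lennard-Jones / electrostatic energy matrices and
# hydrogen-bond occupancies. Energies use Lorentz-Berthelot combination and
# no distance cutoff (the analysed systems are small and image-free).

#' Contact criterion
#'
#' @param distance_cutoff Å; two residues are in contact in a frame when
#'   any atom pair is strictly closer than this (default 4.0).
#' @param sequence_separation only pairs with `j > i + sequence_separation`
#'   are evaluated (default 2, i.e. `j > i + 2`).
#' @return object of class `contact_criterion`.
#' @export
contact_criterion <- function(distance_cutoff = 4.0, sequence_separation = 2L) {
  if (distance_cutoff <= 0) stopf("distance_cutoff must be positive")
  structure(list(distance_cutoff = distance_cutoff,
                 sequence_separation = as.integer(sequence_separation)),
            class = "contact_criterion")
}

#' Hydrogen-bond criterion
#'
#' Geometric criterion: donor-acceptor distance at most
#' `donor_acceptor_cutoff` and H-D...A angle (at the donor, between the
#' D->H and D->A directions) at most `angle_cutoff`.
#'
#' @param donor_acceptor_cutoff Å (default 3.5).
#' @param angle_cutoff degrees in (0, 180) (default 30).
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(donor_acceptor_cutoff = 3.5, angle_cutoff = 30) {
  if (donor_acceptor_cutoff <= 0) stopf("cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff >= 180)
    stopf("angle_cutoff must be in (0, 180)")
  structure(list(donor_acceptor_cutoff = donor_acceptor_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "hbond_criterion")
}

# indices (i of atoms1, j of atoms2) and distances for one frame
.pair_dists <- function(m, a1, a2) {
  d1 <- m[a1, , drop = FALSE]
  d2 <- m[a2, , drop = FALSE]
  dx <- outer(d1[, 1], d2[, 1], "-")
  dy <- outer(d1[, 2], d2[, 2], "-")
  dz <- outer(d1[, 3], d2[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Residue-residue contact-probability map
#'
#' Entry (i, j) is the fraction of frames in which any atom of residue i is
#' strictly closer than the cutoff to any atom of residue j, evaluated only
#' for `j > i + sequence_separation`; excluded entries are `NA`. The matrix
#' is symmetrised.
#'
#' @param traj a [trajectory()].
#' @param crit a [contact_criterion()].
#' @return residue x residue probability matrix with residue-number
#'   dimnames.
#' @export
contact_map <- function(traj, crit = contact_criterion()) {
  res <- peptide_residues(traj)
  nres <- length(res)
  atoms_of <- lapply(res, function(r)
    which(traj$topology$residue_index == r & traj$topology$role == "peptide"))
  P <- matrix(NA_real_, nres, nres, dimnames = list(res, res))
  nf <- n_frames(traj)
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (j <= i + crit$sequence_separation) next
      hits <- 0
      for (f in seq_len(nf)) {
        d <- .pair_dists(frame_coords(traj, f), atoms_of[[i]], atoms_of[[j]])
        if (any(d < crit$distance_cutoff)) hits <- hits + 1
      }
      P[i, j] <- P[j, i] <- hits / nf
    }
  }
  P
}

# LJ + Coulomb energies summed over an atom-pair block, one value per frame
.pair_energy_series <- function(traj, a1, a2) {
  top <- traj$topology
  n1 <- length(a1); n2 <- length(a2)
  sig <- outer(top$lj_sigma[a1], top$lj_sigma[a2], "+") / 2    # arithmetic
  eps <- sqrt(outer(top$lj_epsilon[a1], top$lj_epsilon[a2]))   # geometric
  qq <- outer(top$charge[a1], top$charge[a2])
  nf <- n_frames(traj)
  lj <- numeric(nf); coul <- numeric(nf)
  for (f in seq_len(nf)) {
    r <- .pair_dists(frame_coords(traj, f), a1, a2)
    sr6 <- (sig / r)^6
    lj[f] <- sum(4 * eps * (sr6^2 - sr6))
    coul[f] <- sum(.k_coulomb * qq / r)
  }
  list(lj = lj, coulomb = coul)
}

#' Time-averaged Lennard-Jones and electrostatic energy matrices
#'
#' Residue-pair energies are sums over inter-residue atom pairs of
#' `4*eps_ab*((sig_ab/r)^12 - (sig_ab/r)^6)` and `k_e*q_a*q_b/r`
#' (`k_e = 332.0636` kcal*Å/(mol*e²)), averaged over frames, with
#' Lorentz-Berthelot combination and no distance cutoff. When a ligand is
#' present it appears as an extra row/column labelled `"LIG"`.
#'
#' @param traj a [trajectory()] whose topology carries charges and LJ
#'   parameters.
#' @return list of symmetric matrices `lj` and `coulomb` (kcal/mol, zero
#'   diagonal).
#' @export
pair_energy_matrices <- function(traj) {
  top <- traj$topology
  if (any(!is.finite(top$charge)) || any(!is.finite(top$lj_epsilon)))
    stopf("topology is missing charges or LJ parameters")
  res <- peptide_residues(traj)
  groups <- lapply(res, function(r)
    which(top$residue_index == r & top$role == "peptide"))
  labels <- as.character(res)
  lig <- ligand_atoms(traj)
  if (length(lig)) {
    groups <- c(groups, list(lig))
    labels <- c(labels, "LIG")
  }
  ng <- length(groups)
  LJ <- matrix(0, ng, ng, dimnames = list(labels, labels))
  CO <- matrix(0, ng, ng, dimnames = list(labels, labels))
  for (i in seq_len(ng - 1)) {
    for (j in seq(i + 1, ng)) {
      e <- .pair_energy_series(traj, groups[[i]], groups[[j]])
      LJ[i, j] <- LJ[j, i] <- mean(e$lj)
      CO[i, j] <- CO[j, i] <- mean(e$coulomb)
    }
  }
  list(lj = LJ, coulomb = CO)
}

.angle_deg <- function(v1, v2) {
  c0 <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, c0))) * 180 / pi
}

#' Hydrogen-bond occupancy matrix
#'
#' Per residue pair, the percentage of frames with at least one
#' donor-acceptor pair satisfying the geometric criterion. Donors must come
#' with their attached hydrogen.
#'
#' @param traj a [trajectory()].
#' @param crit an [hbond_criterion()].
#' @param donors `data.frame` with integer columns `donor` and `hydrogen`
#'   (atom indices).
#' @param acceptors integer atom indices.
#' @return symmetric residue x residue occupancy matrix in percent; pairs
#'   within the same residue are not evaluated (0).
#' @export
hbond_occupancy <- function(traj, crit = hbond_criterion(), donors, acceptors) {
  top <- traj$topology
  if (!all(c("donor", "hydrogen") %in% names(donors)))
    stopf("donors must have columns 'donor' and 'hydrogen'")
  if (any(is.na(donors$hydrogen)))
    stopf("donor without an attached hydrogen in topology")
  res <- sort(unique(top$residue_index))
  nres <- length(res)
  occ <- matrix(0, nres, nres, dimnames = list(res, res))
  nf <- n_frames(traj)
  rix <- function(a) match(top$residue_index[a], res)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    bonded <- matrix(FALSE, nres, nres)
    for (k in seq_len(nrow(donors))) {
      d <- donors$donor[k]; h <- donors$hydrogen[k]
      for (a in acceptors) {
        if (top$residue_index[a] == top$residue_index[d]) next
        rda <- sqrt(sum((m[a, ] - m[d, ])^2))
        if (rda > crit$donor_acceptor_cutoff) next
        ang <- .angle_deg(m[h, ] - m[d, ], m[a, ] - m[d, ])
        if (ang <= crit$angle_cutoff) {
          i <- rix(d); j <- rix(a)
          bonded[i, j] <- bonded[j, i] <- TRUE
        }
      }
    }
    occ <- occ + bonded
  }
  100 * occ / nf
}

#' Per-residue peptide-ligand interaction profile
#'
#' Time-averaged Lennard-Jones and electrostatic energies between each
#' peptide residue and the whole ligand, plus hydrogen-bond occupancy when
#' donor/acceptor sets are supplied (0 otherwise, e.g. for coarse-grained
#' beads with no hydrogens).
#'
#' @param traj a [trajectory()] with ligand atoms and parameters.
#' @param crit an [hbond_criterion()].
#' @param donors,acceptors optional; see [hbond_occupancy()].
#' @return `data.frame` with columns `residue`, `lj`, `coulomb`,
#'   `hbond_pct`.
#' @export
peptide_ligand_profile <- function(traj, crit = hbond_criterion(),
                                   donors = NULL, acceptors = NULL) {
  lig <- ligand_atoms(traj)
  if (!length(lig)) stopf("no ligand atoms in trajectory")
  res <- peptide_residues(traj)
  lj <- coul <- hb <- numeric(length(res))
  for (k in seq_along(res)) {
    a <- which(traj$topology$residue_index == res[k] &
                 traj$topology$role == "peptide")
    e <- .pair_energy_series(traj, a, lig)
    lj[k] <- mean(e$lj)
    coul[k] <- mean(e$coulomb)
  }
  if (!is.null(donors) && !is.null(acceptors)) {
    occ <- hbond_occupancy(traj, crit, donors, acceptors)
    ligres <- as.character(unique(traj$topology$residue_index[lig]))
    hb <- apply(occ[as.character(res), ligres, drop = FALSE], 1, max)
  }
  data.frame(residue = res, lj = lj, coulomb = coul, hbond_pct = hb)
}
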