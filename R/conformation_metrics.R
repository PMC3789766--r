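# Chain-dimension statistics (radius of gyration, empirical scaling laws)
# and dihedral-window secondary-structure propensities.

#' Radius of gyration of one frame
#'
#' `sqrt(sum(m_i * |r_i - r_com|^2) / sum(m_i))`; unweighted sets all
#' masses to 1.
#'
#' @param coords `n x 3` coordinate matrix (Å).
#' @param topology topology supplying masses.
#' @param subset 1-based atom indices (non-empty); defaults to all peptide
#'   atoms.
#' @param mass_weighted logical (default `TRUE`).
#' @return Rg in Å.
#' @export
radius_of_gyration <- function(coords, topology,
                               subset = which(topology$role == "peptide"),
                               mass_weighted = TRUE) {
  if (!length(subset)) stopf("subset must be non-empty")
  m <- if (mass_weighted) topology$mass[subset] else rep(1, length(subset))
  x <- coords[subset, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

#' Radius-of-gyration distribution over a trajectory
#'
#' @param traj a [trajectory()] (>= 2 frames for a meaningful sd).
#' @param subset atom indices; defaults to peptide atoms.
#' @param mass_weighted logical.
#' @param breaks passed to [hist()] (number of bins or break points).
#' @return list: `series` (per-frame Rg, Å), `mean`, `sd`, `histogram`
#'   (`data.frame` bin_center, density).
#' @export
rg_distribution <- function(traj, subset = peptide_atoms(traj),
                            mass_weighted = TRUE, breaks = 30) {
  rg <- vapply(seq_len(n_frames(traj)), function(f)
    radius_of_gyration(frame_coords(traj, f), traj$topology, subset,
                       mass_weighted), 0)
  h <- graphics::hist(rg, breaks = breaks, plot = FALSE)
  list(series = rg, mean = mean(rg), sd = stats::sd(rg),
       histogram = data.frame(bin_center = h$mids, density = h$density))
}

#' Empirical chain-dimension scaling law
#'
#' `Rg = prefactor * N^exponent`. The coil law (2.02 Å, 0.6) reproduces the
#' denatured-state expectation of 18.5 Å for a 40-residue chain; the
#' native-regime constants (2.2 Å, 0.38) are conventional folded-state
#' values and carry no printed check.
#'
#' @param prefactor Å (> 0).
#' @param exponent dimensionless, in (0, 1).
#' @param regime `"coil"` or `"native"`.
#' @return object of class `scaling_law`.
#' @export
scaling_law <- function(prefactor, exponent, regime = c("coil", "native")) {
  regime <- match.arg(regime)
  if (prefactor <= 0) stopf("prefactor must be positive")
  if (exponent <= 0 || exponent >= 1) stopf("exponent must be in (0, 1)")
  structure(list(prefactor = prefactor, exponent = exponent, regime = regime),
            class = "scaling_law")
}

#' @rdname scaling_law
#' @export
coil_law <- function() scaling_law(2.02, 0.6, "coil")

#' @rdname scaling_law
#' @export
native_law <- function() scaling_law(2.2, 0.38, "native")

#' Expected radius of gyration from a scaling law
#'
#' @param n_residues chain length (>= 1).
#' @param law a [scaling_law()].
#' @return expected Rg in Å, rounded to 1 decimal.
#' @export
expected_rg <- function(n_residues, law = coil_law()) {
  if (n_residues < 1) stopf("n_residues must be >= 1")
  round(law$prefactor * n_residues^law$exponent, 1)
}

.default_ss_windows <- list(
  H = list(phi = c(-100, -30), psi = c(-80, -5)),
  P = list(phi = c(-110, -50), psi = c(120, 180)),
  E = list(phi = c(-180, -90), psi = c(90, 180))
)

#' Classify residues by backbone dihedral windows
#'
#' @param phi,psi numeric matrices or vectors of dihedrals in degrees (`NA`
#'   where undefined).
#' @param windows list of phi/psi windows for H, P and E (defaults match
#'   the canonical alpha-helical, polyproline-II and extended/beta regions;
#'   E excludes the P window).
#' @param min_helix_run helical labels require runs of at least this many
#'   consecutive residues (default 3); shorter runs revert to coil.
#' @return character labels in {H, E, P, C}, same shape as `phi`.
#' @export
classify_dihedrals <- function(phi, psi, windows = .default_ss_windows,
                               min_helix_run = 3) {
  dims <- dim(phi)
  phi <- as.numeric(phi); psi <- as.numeric(psi)
  inw <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
  lab <- rep("C", length(phi))
  isP <- inw(phi, windows$P$phi) & inw(psi, windows$P$psi)
  isE <- inw(phi, windows$E$phi) & inw(psi, windows$E$psi) & !isP
  isH <- inw(phi, windows$H$phi) & inw(psi, windows$H$psi)
  lab[isE] <- "E"; lab[isP] <- "P"; lab[isH] <- "H"
  if (!is.null(dims)) {
    lab <- matrix(lab, dims[1], dims[2])
    if (min_helix_run > 1) {
      for (f in seq_len(dims[2])) {
        r <- rle(lab[, f] == "H")
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
        for (k in which(r$values & r$lengths < min_helix_run))
          lab[starts[k]:ends[k], f] <- "C"
      }
    }
  }
  lab
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# phi/psi matrices (residues x frames) for atomistic (N/CA/C) or
# coarse-grained (virtual dihedrals over bead quadruplets) input
backbone_dihedrals <- function(traj) {
  top <- traj$topology
  res <- peptide_residues(traj)
  nres <- length(res)
  nf <- n_frames(traj)
  phi <- matrix(NA_real_, nres, nf)
  psi <- matrix(NA_real_, nres, nf)
  idx_of <- function(r, name)
    which(top$residue_index == r & top$atom_name == name &
            top$role == "peptide")[1]
  atomistic <- all(!is.na(vapply(res, function(r)
    idx_of(r, "N"), 0L))) && all(!is.na(vapply(res, function(r)
      idx_of(r, "C"), 0L)))
  if (atomistic) {
    N <- vapply(res, function(r) idx_of(r, "N"), 0L)
    CA <- vapply(res, function(r) idx_of(r, "CA"), 0L)
    C <- vapply(res, function(r) idx_of(r, "C"), 0L)
    for (f in seq_len(nf)) {
      m <- frame_coords(traj, f)
      for (k in seq_len(nres)) {
        if (k > 1)
          phi[k, f] <- .dihedral(m[C[k - 1], ], m[N[k], ], m[CA[k], ], m[C[k], ])
        if (k < nres)
          psi[k, f] <- .dihedral(m[N[k], ], m[CA[k], ], m[C[k], ], m[N[k + 1], ])
      }
    }
  } else {
    # virtual dihedrals over consecutive bead quadruplets
    B <- vapply(res, function(r)
      which(top$residue_index == r & top$role == "peptide")[1], 0L)
    for (f in seq_len(nf)) {
      m <- frame_coords(traj, f)
      for (k in seq_len(nres)) {
        if (k >= 3 && k < nres)
          phi[k, f] <- .dihedral(m[B[k - 2], ], m[B[k - 1], ], m[B[k], ],
                                 m[B[k + 1], ])
        if (k >= 2 && k <= nres - 2)
          psi[k, f] <- .dihedral(m[B[k - 1], ], m[B[k], ], m[B[k + 1], ],
                                 m[B[k + 2], ])
      }
    }
  }
  list(phi = phi, psi = psi)
}

#' Assign secondary structure from backbone dihedrals
#'
#' Dihedral-window (mesostate) assignment: helix (H), extended/sheet (E),
#' polyproline II (P), else coil (C). Helix requires runs of >= 3
#' consecutive helical residues; residues lacking either dihedral (chain
#' termini) are coil. Atomistic input uses true phi/psi over N/CA/C;
#' coarse-grained input uses virtual dihedrals over bead quadruplets.
#'
#' @param traj a [trajectory()].
#' @param windows,min_helix_run see [classify_dihedrals()].
#' @return object of class `ss_assignment`: character matrix `labels`
#'   (residues x frames) with residue-number rownames.
#' @export
assign_secondary_structure <- function(traj, windows = .default_ss_windows,
                                       min_helix_run = 3) {
  dh <- backbone_dihedrals(traj)
  both <- !is.na(dh$phi) & !is.na(dh$psi)
  lab <- classify_dihedrals(dh$phi, dh$psi, windows, min_helix_run)
  lab[!both] <- "C"
  rownames(lab) <- peptide_residues(traj)
  structure(list(labels = lab), class = "ss_assignment")
}

#' Secondary-structure content and per-residue helix propensity
#'
#' @param assign an [assign_secondary_structure()] result.
#' @return list: `content` (`data.frame` class, mean_pct, sd_pct over
#'   per-frame fractions) and `helix_propensity` (named per-residue
#'   fraction of frames labelled H).
#' @export
ss_content_and_propensity <- function(assign) {
  lab <- assign$labels
  classes <- c("H", "E", "P", "C")
  frac <- vapply(classes, function(cl) colMeans(lab == cl),
                 numeric(ncol(lab)))
  frac <- matrix(frac, ncol = length(classes),
                 dimnames = list(NULL, classes))
  content <- data.frame(
    class = classes,
    mean_pct = 100 * apply(frac, 2, mean),
    sd_pct = 100 * apply(frac, 2, function(x) if (length(x) > 1) sd(x) else 0)
  )
  rownames(content) <- NULL
  list(content = content,
       helix_propensity = rowMeans(lab == "H"))
}
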