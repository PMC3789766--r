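#' Kabsch superposition
#'
#' Least-squares optimal proper rigid superposition of `mobile` onto
#' `reference` over the atoms in `subset`, via the SVD of the covariance
#' matrix with the reflection corrected to keep the rotation proper
#' (determinant +1). The transform maps a mobile row-vector `x` to
#' `x %*% t(rotation) + translation`.
#'
#' @param mobile,reference `n x 3` coordinate matrices.
#' @param subset 1-based atom indices (>= 3 non-collinear atoms).
#' @return object of class `superposition`: `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Å over the subset).
#' @export
kabsch_superpose <- function(mobile, reference,
                             subset = seq_len(nrow(mobile))) {
  if (length(subset) < 3) stopf("subset must contain at least 3 atoms")
  A <- mobile[subset, , drop = FALSE]
  B <- reference[subset, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))  # 3x3; rotation R = U diag(1,1,d) V'
  if (s$d[2] < 1e-10 * max(s$d[1], 1))
    stopf("degenerate (collinear) atom subset for superposition")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- cb - as.numeric(R %*% ca)
  Arot <- A %*% t(R) + matrix(tr, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Arot - B)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp a [kabsch_superpose()] result.
#' @param coords `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sp, coords) {
  coords %*% t(sp$rotation) +
    matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

#' All-pairs superposed RMSD matrix
#'
#' Entry (i, j) is the Kabsch-minimal RMSD between frames i and j over the
#' atom subset; the diagonal is zero and the matrix symmetric.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param subset 1-based atom indices; defaults to [backbone_atoms()].
#' @return symmetric `n_frames x n_frames` matrix (Å).
#' @export
pairwise_rmsd_matrix <- function(traj, subset = backbone_atoms(traj)) {
  if (n_frames(traj) < 2) stopf("need at least 2 frames")
  if (length(subset) < 3) stopf("subset must contain at least 3 atoms")
  .pairwise_rmsd_cpp(traj$coords, as.integer(subset))
}

#' Daura (GROMOS-style) RMSD clustering
#'
#' Iterative greedy scheme: the frame with the most neighbours (frames
#' within `cutoff` RMSD) becomes a cluster representative, it and its
#' neighbours form the cluster and are removed, and the count is repeated
#' on the remainder. Ties on neighbour count are broken by the lowest frame
#' index. Populations are fractions of all frames, so cluster sizes are
#' non-increasing and populations sum to 1.
#'
#' @param rmsd square symmetric matrix from [pairwise_rmsd_matrix()].
#' @param cutoff neighbour cutoff, Å (2.0 for backbone clustering).
#' @return object of class `cluster_set`: `assignment` (frame -> cluster
#'   id, clusters numbered by decreasing population), `populations`,
#'   `sizes`, `representatives` (frame indices).
#' @export
daura_cluster <- function(rmsd, cutoff = 2.0) {
  n <- nrow(rmsd)
  if (is.null(n) || n == 0) stopf("empty RMSD matrix")
  if (ncol(rmsd) != n || max(abs(rmsd - t(rmsd))) > 1e-8)
    stopf("RMSD matrix must be square and symmetric")
  adj <- rmsd <= cutoff
  diag(adj) <- FALSE
  remaining <- rep(TRUE, n)
  assignment <- integer(n)
  reps <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- colSums(adj[remaining, , drop = FALSE]) # neighbours among remaining
    counts[!remaining] <- -1L
    center <- which.max(counts)  # lowest index wins ties
    members <- which(remaining & (adj[, center] | seq_len(n) == center))
    assignment[members] <- cl
    reps[cl] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(assignment, nbins = cl)
  structure(list(assignment = assignment, populations = sizes / n,
                 sizes = sizes, representatives = reps),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d frames\n",
              length(x$sizes), length(x$assignment)))
  print(utils::head(data.frame(cluster = seq_along(x$sizes),
                               size = x$sizes,
                               population_pct = round(100 * x$populations, 1),
                               representative = x$representatives), 10))
  invisible(x)
}

#' Ligand cloud per conformational cluster
#'
#' For each cluster, every member frame's peptide is superposed onto the
#' cluster representative and the same rigid transform is applied to the
#' ligand atoms; the cloud is the list of mass-weighted ligand centres of
#' mass, one per member frame, in the representative's coordinate frame.
#'
#' @param traj a [trajectory()] with ligand atoms.
#' @param clusters a [daura_cluster()] result computed on this trajectory's
#'   peptide subset.
#' @param subset peptide atom subset used for superposition; defaults to
#'   [backbone_atoms()].
#' @return object of class `ligand_cloud`: a list (one per cluster) of
#'   `n_members x 3` matrices of ligand centre-of-mass coordinates (Å).
#' @export
ligand_cloud <- function(traj, clusters, subset = backbone_atoms(traj)) {
  lig <- ligand_atoms(traj)
  if (!length(lig)) stopf("ligand_cloud requires ligand atoms")
  lm <- traj$topology$mass[lig]
  out <- vector("list", length(clusters$sizes))
  for (cl in seq_along(clusters$sizes)) {
    members <- which(clusters$assignment == cl)
    ref <- frame_coords(traj, clusters$representatives[cl])
    pts <- matrix(NA_real_, length(members), 3)
    for (k in seq_along(members)) {
      m <- frame_coords(traj, members[k])
      sp <- kabsch_superpose(m, ref, subset)
      ligxyz <- apply_superposition(sp, m[lig, , drop = FALSE])
      pts[k, ] <- colSums(ligxyz * lm) / sum(lm)
    }
    out[[cl]] <- pts
  }
  structure(out, class = "ligand_cloud")
}

#' Cluster population report
#'
#' Top-k cluster populations as percentages (1 decimal) with their
#' cumulative occupancy rounded half-up to the nearest integer percent —
#' the convention behind statements such as "the top eight clusters cover
#' about 77% of the bound ensemble versus 50% unbound".
#'
#' @param clusters a [daura_cluster()] result, or a numeric vector of
#'   population fractions.
#' @param top_k number of leading clusters to report (>= 1; capped at the
#'   cluster count).
#' @return list: `table` (`data.frame` cluster, population_pct,
#'   representative when known) and `cumulative_pct` (integer).
#' @export
cluster_population_report <- function(clusters, top_k = 8) {
  if (top_k < 1) stopf("top_k must be >= 1")
  if (inherits(clusters, "cluster_set")) {
    pops <- clusters$populations
    reps <- clusters$representatives
  } else {
    pops <- as.numeric(clusters)
    reps <- rep(NA_integer_, length(pops))
  }
  k <- min(top_k, length(pops))
  ord <- order(-pops)[seq_len(k)]
  pct <- round(100 * pops[ord], 1)
  list(
    table = data.frame(cluster = ord, population_pct = pct,
                       representative = reps[ord]),
    cumulative_pct = as.integer(round_half_up(sum(100 * pops[ord])))
  )
}
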