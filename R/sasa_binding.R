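#' Shrake-Rupley SASA parameters
#'
#' @param probe_radius solvent probe radius, Å (water: 1.4).
#' @param n_sphere_points number of quasi-uniform sphere points per atom
#'   (golden-spiral construction, deterministic; >= 12).
#' @return object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 256) {
  if (probe_radius < 0) stopf("probe_radius must be >= 0")
  if (n_sphere_points < 12) stopf("n_sphere_points must be >= 12")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "sasa_params")
}

#' Shrake-Rupley solvent accessible surface area
#'
#' For each atom in `subset`, the accessible area is
#' `4*pi*(r+w)^2` times the fraction of sphere points at radius `r+w` not
#' strictly inside any other subset atom's probe-expanded sphere. Only atoms
#' in `subset` occlude.
#'
#' @param coords `n_atoms x 3` matrix (Å) or a [trajectory()] frame via
#'   [frame_coords()].
#' @param topology topology `data.frame` supplying radii.
#' @param subset 1-based atom indices (default: all atoms).
#' @param params a [sasa_params()].
#' @return named numeric, per-atom area in Å² for the subset atoms.
#' @export
shrake_rupley_sasa <- function(coords, topology, subset = seq_len(nrow(topology)),
                               params = sasa_params()) {
  if (!length(subset)) stopf("subset must be non-empty")
  validate_topology(topology)
  a <- .sasa_cpp(coords, topology$radius, as.integer(subset),
                 params$probe_radius, params$n_sphere_points)
  setNames(a, topology$atom_name[subset])
}

#' Per-residue, per-frame ligand-occlusion surface (delta-SASA)
#'
#' For every frame and peptide residue, delta-SASA is the residue's SASA
#' computed over the peptide atoms alone (ligand deleted, coordinates
#' unchanged) minus its SASA in the full complex, summed over the residue's
#' atoms. The unbound reference is frame-local, so the difference is exactly
#' the surface buried by the ligand and is non-negative by construction.
#'
#' @param traj a [trajectory()] containing at least one ligand atom.
#' @param params a [sasa_params()].
#' @return object of class `delta_sasa_series`: matrix `values`
#'   (residues x frames, Å²), `residues`, `times`, `time_spacing`.
#' @export
delta_sasa <- function(traj, params = sasa_params()) {
  if (!length(ligand_atoms(traj)))
    stopf("delta_sasa requires a trajectory with ligand atoms")
  res <- peptide_residues(traj)
  vals <- .delta_sasa_cpp(traj$coords, traj$topology$radius,
                          traj$topology$role == "peptide",
                          as.integer(traj$topology$residue_index),
                          as.integer(res),
                          params$probe_radius, params$n_sphere_points)
  dimnames(vals) <- list(res, NULL)
  structure(list(values = vals, residues = res, times = traj$times,
                 time_spacing = traj$time_spacing),
            class = "delta_sasa_series")
}

#' Segment per-residue binding events from a delta-SASA series
#'
#' A residue is bound in a frame when its delta-SASA strictly exceeds
#' `threshold` (default 10 Å²). Events are maximal runs of consecutive
#' bound frames; one sub-threshold frame terminates a run. Runs shorter
#' than `min_duration` (default 10 ns) are discarded. Event duration is
#' run length times the frame spacing; `end_time` is exclusive
#' (`start_time + duration`).
#'
#' @param series a [delta_sasa()] result.
#' @param threshold Å².
#' @param min_duration ns.
#' @return `data.frame` with columns `residue_index`, `start_time` (ps),
#'   `end_time` (ps), `n_frames`, `duration` (ns).
#' @export
segment_events <- function(series, threshold = 10, min_duration = 10) {
  dt <- series$time_spacing
  if (min_duration * 1000 < dt)
    warning("min_duration is below the frame spacing; no events are filtered")
  out <- list()
  for (k in seq_along(series$residues)) {
    bound <- series$values[k, ] > threshold
    r <- rle(bound)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (any(keep)) {
      len <- r$lengths[keep]
      dur_ns <- len * dt / 1000
      ok <- dur_ns >= min_duration
      if (any(ok)) {
        s <- starts[keep][ok]
        out[[length(out) + 1]] <- data.frame(
          residue_index = series$residues[k],
          start_time = series$times[s],
          end_time = series$times[s] + len[ok] * dt,
          n_frames = len[ok],
          duration = dur_ns[ok]
        )
      }
    }
  }
  if (!length(out))
    return(data.frame(residue_index = integer(), start_time = numeric(),
                      end_time = numeric(), n_frames = integer(),
                      duration = numeric()))
  do.call(rbind, out)
}

#' Per-residue binding-time percentage
#'
#' The percentage of frames a residue spends inside retained binding
#' events: `100 * frames-in-events / n_frames`.
#'
#' @param events event table from [segment_events()] (already
#'   duration-filtered).
#' @param n_frames total frame count (> 0).
#' @param residues residue numbers to report (residues without events get
#'   0%).
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
binding_percentage <- function(events, n_frames, residues) {
  if (n_frames < 1) stopf("n_frames must be positive")
  pct <- setNames(rep(0, length(residues)), residues)
  if (nrow(events)) {
    agg <- tapply(events$n_frames, events$residue_index, sum)
    pct[names(agg)] <- 100 * as.numeric(agg) / n_frames
  }
  pct
}

#' Call contiguous binding sites from per-residue percentages
#'
#' Residues at or above `min_pct` are merged into contiguous ranges,
#' bridging gaps of at most `max_gap` sub-threshold residues; ranges are
#' ranked by the mean percentage over their residues.
#'
#' @param percentages named numeric from [binding_percentage()] (names are
#'   residue numbers).
#' @param min_pct minimum binding percentage for a residue to seed a site.
#' @param max_gap residues; sub-threshold gap bridged inside one site.
#' @return `data.frame` with `start`, `end`, `mean_pct`, `rank` (1 =
#'   strongest), ordered by rank.
#' @export
call_sites <- function(percentages, min_pct = 20, max_gap = 1) {
  res <- as.integer(names(percentages))
  hot <- which(percentages >= min_pct)
  if (!length(hot))
    return(data.frame(start = integer(), end = integer(),
                      mean_pct = numeric(), rank = integer()))
  gaps <- diff(hot)
  newgrp <- c(TRUE, gaps > max_gap + 1)
  grp <- cumsum(newgrp)
  sites <- do.call(rbind, lapply(split(hot, grp), function(ix) {
    lo <- min(ix); hi <- max(ix)
    data.frame(start = res[lo], end = res[hi],
               mean_pct = mean(percentages[lo:hi]))
  }))
  sites <- sites[order(-sites$mean_pct), , drop = FALSE]
  sites$rank <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  sites
}

#' One-call binding summary
#'
#' Runs [delta_sasa()], [segment_events()], [binding_percentage()] and
#' [call_sites()] on a trajectory. `count_unfiltered = TRUE` computes
#' percentages from the raw per-frame mask instead of the duration-filtered
#' events (both orders of the two published rules are supported; the
#' filtered-first composition is the default).
#'
#' @param traj a [trajectory()] with a ligand.
#' @param threshold Å²; see [segment_events()].
#' @param min_duration ns; see [segment_events()].
#' @param min_pct,max_gap see [call_sites()].
#' @param params a [sasa_params()].
#' @param count_unfiltered logical.
#' @return list with `series`, `events`, `percentages`, `sites`.
#' @export
binding_summary <- function(traj, threshold = 10, min_duration = 10,
                            min_pct = 20, max_gap = 1,
                            params = sasa_params(),
                            count_unfiltered = FALSE) {
  series <- delta_sasa(traj, params)
  events <- segment_events(series, threshold, min_duration)
  if (count_unfiltered) {
    pct <- 100 * rowMeans(series$values > threshold)
  } else {
    pct <- binding_percentage(events, n_frames = ncol(series$values),
                              residues = series$residues)
  }
  list(series = series, events = events, percentages = pct,
       sites = call_sites(pct, min_pct, max_gap))
}
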