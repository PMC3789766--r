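# End-to-end pipeline: obtain a trajectory (synthetic run or PDB+topology
# input), run the enabled analysis stages in dependency order, write tidy
# tab-separated outputs and a manifest, and render a text summary.

#' Build a validated pipeline run configuration
#'
#' Exactly one of `pdb`/`synthetic` must be given. All stage parameters
#' default to the published analysis settings: delta-SASA threshold 10 Å²,
#' 10 ns minimum event duration, 2.0 Å backbone-RMSD cluster cutoff, 4.0 Å
#' contact cutoff with `j > i + 2`, 200 ps MM/PBSA block cadence, 300 K.
#'
#' @param pdb optional list `list(path=, topology=, chain_roles=,
#'   time_spacing=)` describing a multi-model PDB input (`topology` path
#'   optional).
#' @param synthetic optional list `list(chain=, ligand=, params=)` of
#'   [chain_spec()], [ligand_spec()] (or `NULL`) and [simulation_params()].
#' @param stages character subset of `c("binding", "clustering",
#'   "interactions", "metrics", "energetics")`.
#' @param outdir output directory (created if missing).
#' @param sasa_threshold delta-SASA binding threshold, Å².
#' @param min_duration_ns minimum binding-event duration, ns.
#' @param min_pct,max_gap site-calling parameters; see [call_sites()].
#' @param rmsd_cutoff clustering cutoff, Å.
#' @param contact_cutoff contact distance cutoff, Å.
#' @param sequence_separation contact rule `j > i + sequence_separation`.
#' @param block_ps MM/PBSA block length, ps.
#' @param temperature K, for affinity ratios.
#' @param thermo_table optional path to a [read_thermo_table()] file.
#' @param sasa a [sasa_params()].
#' @return object of class `run_config`.
#' @export
run_config <- function(pdb = NULL, synthetic = NULL,
                       stages = c("binding", "clustering", "interactions",
                                  "metrics", "energetics"),
                       outdir = tempfile("ligandcloud_run_"),
                       sasa_threshold = 10, min_duration_ns = 10,
                       min_pct = 20, max_gap = 1,
                       rmsd_cutoff = 2.0, contact_cutoff = 4.0,
                       sequence_separation = 2L, block_ps = 200,
                       temperature = 300, thermo_table = NULL,
                       sasa = sasa_params()) {
  if (is.null(pdb) == is.null(synthetic))
    stopf("exactly one of 'pdb' or 'synthetic' must be supplied")
  stages <- match.arg(stages, several.ok = TRUE)
  if (sasa_threshold < 0 || min_duration_ns < 0 || rmsd_cutoff <= 0 ||
      contact_cutoff <= 0 || temperature <= 0)
    stopf("stage parameters out of range")
  structure(list(pdb = pdb, synthetic = synthetic, stages = stages,
                 outdir = outdir, sasa_threshold = sasa_threshold,
                 min_duration_ns = min_duration_ns, min_pct = min_pct,
                 max_gap = max_gap, rmsd_cutoff = rmsd_cutoff,
                 contact_cutoff = contact_cutoff,
                 sequence_separation = as.integer(sequence_separation),
                 block_ps = block_ps, temperature = temperature,
                 thermo_table = thermo_table, sasa = sasa),
            class = "run_config")
}

.write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_matrix <- function(m, dir, name) {
  path <- file.path(dir, name)
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order (simulate/load, binding, clustering,
#' interactions, metrics, energetics); each stage's tables are written
#' under `config$outdir` and listed in the report manifest together with a
#' provenance block (parameters + seed) sufficient to re-run the seeded
#' stages bit-identically. A stage failure aborts with the failing stage
#' named. Progress is logged to `stderr`.
#'
#' @param config a [run_config()].
#' @return object of class `ligandcloud_report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), file = character())
  add <- function(stage, path)
    manifest <<- rbind(manifest, data.frame(stage = stage, file = path))
  results <- list()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[ligandcloud] stage %-12s %6.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  traj <- run_stage("input", {
    if (!is.null(config$synthetic)) {
      s <- config$synthetic
      simulate_cg(s$chain, s$ligand, s$params %||% simulation_params())
    } else {
      tr <- read_pdb_models(config$pdb$path, config$pdb$chain_roles,
                            config$pdb$time_spacing %||% 20)
      if (!is.null(config$pdb$topology))
        tr <- attach_topology(tr, read_topology(config$pdb$topology))
      tr
    }
  })
  has_ligand <- length(ligand_atoms(traj)) > 0

  if ("binding" %in% config$stages && has_ligand) {
    bs <- run_stage("binding", binding_summary(
      traj, threshold = config$sasa_threshold,
      min_duration = config$min_duration_ns,
      min_pct = config$min_pct, max_gap = config$max_gap,
      params = config$sasa))
    results$binding <- bs
    add("binding", .write_tsv(bs$events, config$outdir, "binding_events.tsv"))
    add("binding", .write_tsv(
      data.frame(residue = as.integer(names(bs$percentages)),
                 binding_pct = bs$percentages),
      config$outdir, "binding_percentage.tsv"))
    add("binding", .write_tsv(bs$sites, config$outdir, "binding_sites.tsv"))
  }

  if ("clustering" %in% config$stages) {
    cls <- run_stage("clustering", {
      rm <- pairwise_rmsd_matrix(traj)
      daura_cluster(rm, cutoff = config$rmsd_cutoff)
    })
    results$clusters <- cls
    add("clustering", .write_tsv(
      data.frame(cluster = seq_along(cls$sizes), size = cls$sizes,
                 population_pct = round(100 * cls$populations, 1),
                 representative = cls$representatives),
      config$outdir, "clusters.tsv"))
    add("clustering", .write_tsv(
      data.frame(frame = seq_along(cls$assignment),
                 cluster = cls$assignment),
      config$outdir, "cluster_assignment.tsv"))
    if (has_ligand) {
      cloud <- run_stage("ligand_cloud", ligand_cloud(traj, cls))
      results$cloud <- cloud
      pts <- do.call(rbind, lapply(seq_along(cloud), function(cl)
        data.frame(cluster = cl, x = cloud[[cl]][, 1],
                   y = cloud[[cl]][, 2], z = cloud[[cl]][, 3])))
      add("clustering", .write_tsv(pts, config$outdir, "ligand_cloud.tsv"))
    }
  }

  if ("interactions" %in% config$stages) {
    ia <- run_stage("interactions", {
      crit <- contact_criterion(config$contact_cutoff,
                                config$sequence_separation)
      out <- list(contacts = contact_map(traj, crit),
                  energies = pair_energy_matrices(traj))
      if (has_ligand) out$profile <- peptide_ligand_profile(traj)
      out
    })
    results$interactions <- ia
    add("interactions", .write_matrix(ia$contacts, config$outdir,
                                      "contact_map.tsv"))
    add("interactions", .write_matrix(ia$energies$lj, config$outdir,
                                      "lj_matrix.tsv"))
    add("interactions", .write_matrix(ia$energies$coulomb, config$outdir,
                                      "coulomb_matrix.tsv"))
    if (has_ligand)
      add("interactions", .write_tsv(ia$profile, config$outdir,
                                     "peptide_ligand_profile.tsv"))
  }

  if ("metrics" %in% config$stages) {
    mt <- run_stage("metrics", {
      rg <- rg_distribution(traj)
      ss <- ss_content_and_propensity(assign_secondary_structure(traj))
      list(rg = rg, ss = ss)
    })
    results$metrics <- mt
    add("metrics", .write_tsv(
      data.frame(frame = seq_along(mt$rg$series), rg = mt$rg$series),
      config$outdir, "rg_series.tsv"))
    add("metrics", .write_tsv(mt$ss$content, config$outdir,
                              "ss_content.tsv"))
    add("metrics", .write_tsv(
      data.frame(residue = as.integer(names(mt$ss$helix_propensity)),
                 helix_propensity = mt$ss$helix_propensity),
      config$outdir, "helix_propensity.tsv"))
  }

  if ("energetics" %in% config$stages && !is.null(config$thermo_table)) {
    en <- run_stage("energetics", {
      recs <- read_thermo_table(config$thermo_table)
      cmps <- list()
      labs <- names(recs)
      for (i in seq_along(recs))
        for (j in seq_along(recs))
          if (i < j)
            cmps[[paste(labs[i], "vs", labs[j])]] <-
              compare_thermo(recs[[i]], recs[[j]], config$temperature)
      list(records = recs, comparisons = cmps)
    })
    results$energetics <- en
    cmp_df <- do.call(rbind, lapply(names(en$comparisons), function(nm) {
      x <- en$comparisons[[nm]]
      data.frame(comparison = nm, ddG = x$ddG, ddH = x$ddH, dU = x$dU,
                 affinity_ratio = x$affinity_ratio)
    }))
    add("energetics", .write_tsv(cmp_df, config$outdir,
                                 "thermo_comparisons.tsv"))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("ligandcloud")),
    seed = if (!is.null(config$synthetic))
      (config$synthetic$params %||% simulation_params())$seed else NA,
    parameters = config[c("sasa_threshold", "min_duration_ns", "min_pct",
                          "max_gap", "rmsd_cutoff", "contact_cutoff",
                          "sequence_separation", "block_ps", "temperature")]
  )
  missing <- manifest$file[!file.exists(manifest$file)]
  if (length(missing))
    stopf("manifest lists missing file(s): %s", paste(missing, collapse = ", "))
  structure(list(manifest = manifest, provenance = provenance,
                 results = results, outdir = config$outdir),
            class = "ligandcloud_report")
}

#' Render a report as a human-readable summary
#'
#' Deterministic markdown text: called binding sites, top cluster
#' populations with their cumulative occupancy, and thermodynamic
#' comparisons. Sections for stages that did not run are omitted.
#'
#' @param report a [run_pipeline()] result.
#' @param top_k clusters to list.
#' @return character scalar (markdown).
#' @export
render_report <- function(report, top_k = 8) {
  if (!inherits(report, "ligandcloud_report"))
    stopf("report must come from run_pipeline()")
  missing <- report$manifest$file[!file.exists(report$manifest$file)]
  if (length(missing))
    stopf("missing manifest entries: %s", paste(missing, collapse = ", "))
  ln <- c("# ligandcloud analysis summary", "")
  r <- report$results
  if (!is.null(r$binding)) {
    ln <- c(ln, "## Binding sites (delta-SASA)", "")
    if (nrow(r$binding$sites)) {
      ln <- c(ln, sprintf("- site %d: residues %d-%d (mean binding %.1f%%)",
                          r$binding$sites$rank, r$binding$sites$start,
                          r$binding$sites$end, r$binding$sites$mean_pct))
    } else ln <- c(ln, "- no sites called")
    ln <- c(ln, "")
  }
  if (!is.null(r$clusters)) {
    rep_k <- cluster_population_report(r$clusters, top_k)
    ln <- c(ln, sprintf("## Conformational clusters (top %d)",
                        nrow(rep_k$table)), "",
            sprintf("- cluster %d: %.1f%% (representative frame %d)",
                    rep_k$table$cluster, rep_k$table$population_pct,
                    rep_k$table$representative),
            sprintf("- cumulative occupancy: %d%%", rep_k$cumulative_pct),
            "")
  }
  if (!is.null(r$energetics)) {
    ln <- c(ln, "## Thermodynamic comparisons", "",
            vapply(r$energetics$comparisons, function(x)
              sprintf("- %s vs %s: ddG %.1f, ddH %.1f, dU %.1f kcal/mol (ratio %.1f)",
                      x$labels[1], x$labels[2], x$ddG, x$ddH, x$dU,
                      x$affinity_ratio), ""),
            "")
  }
  paste(ln, collapse = "\n")
}
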