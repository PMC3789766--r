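# MM/PBSA-style free-energy bookkeeping: dG = dH - T*dS with linear
# (sum-of-sd) uncertainty propagation, record comparisons (ddG, ddH, dU,
# affinity ratio) and block averaging of energy series. The Poisson-
# Boltzmann and entropy machinery behind dH / TdS is out of scope; records
# are ingested from tables (or from gas-phase terms computed elsewhere in
# the package).

#' Combine enthalpy and entropy into a free energy
#'
#' `value = dH - TdS`, rounded to 1 decimal; the uncertainty is the linear
#' sum of the input sds (also 1 decimal). The linear rule, not quadrature,
#' is the convention used by the summary tables this module mirrors.
#'
#' @param dH,TdS length-2 numerics `c(value, sd)` in kcal/mol.
#' @return list with `value` and `sd` (kcal/mol).
#' @export
free_energy <- function(dH, TdS) {
  if (dH[2] < 0 || TdS[2] < 0) stopf("standard deviations must be >= 0")
  list(value = round(dH[1] - TdS[1], 1), sd = round(dH[2] + TdS[2], 1))
}

#' Thermodynamic record for one peptide-ligand system
#'
#' @param label text, e.g. `"c-Myc_370-409/S"`.
#' @param dH,TdS,u_nonbonded length-2 `c(value, sd)` in kcal/mol
#'   (`u_nonbonded` optional).
#' @param dG optional length-2 `c(value, sd)`; when omitted it is computed
#'   with [free_energy()]. Supplying it allows a table's printed value to
#'   be preserved verbatim even when it disagrees with `dH - TdS` at the
#'   last printed digit.
#' @return object of class `thermo_record`.
#' @export
thermo_record <- function(label, dH, TdS, dG = NULL, u_nonbonded = NULL) {
  if (is.null(dG)) {
    fe <- free_energy(dH, TdS)
    dG <- c(fe$value, fe$sd)
  }
  structure(list(label = label, dH = dH, TdS = TdS, dG = dG,
                 u_nonbonded = u_nonbonded),
            class = "thermo_record")
}

#' Compare two thermodynamic records
#'
#' Differences `a - b` of dG, dH and the averaged non-bonded potential,
#' plus the implied affinity ratio `exp(-ddG / (kB*T))` with
#' `kB = 0.0019872` kcal/mol/K.
#'
#' @param a,b [thermo_record()] objects.
#' @param temperature K (default 300).
#' @return object of class `thermo_comparison`: `ddG`, `ddH`, `dU`
#'   (kcal/mol; `dU` is `NA` if either record lacks `u_nonbonded`),
#'   `affinity_ratio`, `temperature`.
#' @export
compare_thermo <- function(a, b, temperature = 300) {
  ddG <- a$dG[1] - b$dG[1]
  ddH <- a$dH[1] - b$dH[1]
  dU <- if (!is.null(a$u_nonbonded) && !is.null(b$u_nonbonded))
    a$u_nonbonded[1] - b$u_nonbonded[1] else NA_real_
  structure(list(labels = c(a$label, b$label), ddG = ddG, ddH = ddH,
                 dU = dU, affinity_ratio = exp(-ddG / (.kB * temperature)),
                 temperature = temperature),
            class = "thermo_comparison")
}

#' @export
print.thermo_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: ddG = %.1f, ddH = %.1f, dU = %.1f kcal/mol; affinity ratio %.1f (T = %g K)\n",
              x$labels[1], x$labels[2], x$ddG, x$ddH, x$dU,
              x$affinity_ratio, x$temperature))
  invisible(x)
}

#' Block statistics of an energy series
#'
#' Partitions the series into contiguous blocks of `block` ps (a trailing
#' partial block is dropped) and reports the mean of block means and their
#' standard deviation. With a single block the sd is reported as 0 with
#' `insufficient_data = TRUE`.
#'
#' @param values numeric, one energy per sampled frame (kcal/mol).
#' @param sampling_interval ps between samples.
#' @param block block length in ps (>= `sampling_interval`).
#' @return list: `mean`, `sd`, `n_blocks`, `insufficient_data`.
#' @export
block_stats <- function(values, sampling_interval, block = 200) {
  if (block < sampling_interval)
    stopf("block length must be >= the sampling interval")
  if (!length(values)) stopf("empty energy series")
  per <- max(1L, floor(block / sampling_interval))
  nb <- floor(length(values) / per)
  if (nb < 1) { per <- length(values); nb <- 1L }
  bm <- vapply(seq_len(nb), function(b)
    mean(values[((b - 1) * per + 1):(b * per)]), 0)
  list(mean = mean(bm),
       sd = if (nb > 1) stats::sd(bm) else 0,
       n_blocks = nb,
       insufficient_data = nb < 2)
}

#' Read a thermodynamic summary table
#'
#' Tab-separated text with header columns `peptide`, `chirality`, `dH`,
#' `dH_sd`, `TdS`, `TdS_sd`, `dG`, `dG_sd`, `u_nb`, `u_nb_sd` (kcal/mol;
#' typographic minus accepted). Each row becomes a [thermo_record()] whose
#' printed `dG` is preserved verbatim.
#'
#' @param path file path; defaults to the packaged c-Myc/10074-A4 MM/PBSA
#'   summary.
#' @return named list of [thermo_record()] objects
#'   (`"<peptide>/<chirality>"`).
#' @export
read_thermo_table <- function(path = system.file("extdata",
                                                 "myc_10074A4_mmpbsa.tsv",
                                                 package = "ligandcloud")) {
  raw <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  num <- c("dH", "dH_sd", "TdS", "TdS_sd", "dG", "dG_sd", "u_nb", "u_nb_sd")
  for (cn in num) raw[[cn]] <- parse_numeric(raw[[cn]])
  recs <- lapply(seq_len(nrow(raw)), function(i) {
    thermo_record(
      label = paste0(raw$peptide[i], "/", raw$chirality[i]),
      dH = c(raw$dH[i], raw$dH_sd[i]),
      TdS = c(raw$TdS[i], raw$TdS_sd[i]),
      dG = c(raw$dG[i], raw$dG_sd[i]),
      u_nonbonded = c(raw$u_nb[i], raw$u_nb_sd[i])
    )
  })
  setNames(recs, vapply(recs, `[[`, "", "label"))
}
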