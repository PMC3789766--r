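#' Sequence records and the charged-residue census
#'
#' `sequence_record()` holds a one-letter amino-acid sequence with its input
#' numbering (e.g. a c-Myc segment starting at residue 370).
#'
#' @param identifier short label.
#' @param residues one-letter amino-acid string (20 standard letters).
#' @param start_number residue number of the first position.
#' @return object of class `sequence_record`.
#' @export
sequence_record <- function(identifier, residues, start_number = 1L) {
  residues <- toupper(residues)
  if (!nzchar(residues)) stopf("sequence must be non-empty")
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(chars, letters20)
  if (length(bad))
    stopf("non-standard residue letter(s): %s", paste(unique(bad), collapse = ""))
  structure(list(identifier = identifier, residues = residues,
                 start_number = as.integer(start_number)),
            class = "sequence_record")
}

#' Count charged residues in a sequence
#'
#' Counts residues in the charged set D, E, K, R. Histidine is treated as
#' neutral: for the c-Myc 370-409 segment this convention reproduces the
#' census of 12 charged residues out of 40.
#'
#' @param seq a [sequence_record()] or a plain one-letter string.
#' @return integer count.
#' @export
count_charged_residues <- function(seq) {
  if (inherits(seq, "sequence_record")) seq <- seq$residues
  seq <- sequence_record("tmp", seq)$residues  # validate letters
  sum(strsplit(seq, "")[[1]] %in% c("D", "E", "K", "R"))
}

#' Built-in study sequences
#'
#' The two c-Myc bHLHZip segments analysed by the pipeline: the 10074-A4
#' binder c-Myc 370-409 and the non-binding control segment 410-437.
#'
#' @return named list of [sequence_record()] objects.
#' @export
myc_sequences <- function() {
  list(
    myc_370_409 = sequence_record(
      "c-Myc_370-409", "LKRSFFALRDQIPELENNEKAPKVVILKKATAYILSVQAE", 370L),
    myc_410_437 = sequence_record(
      "c-Myc_410-437", "EQKLISEEDLLRKRREQLKHKLEQLRNS", 410L)
  )
}
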