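# Utilities for the oligonucleotide table used to amplify genome-spanning
# cDNA fragments.

#' Read an oligonucleotide table
#'
#' Expects a TSV with columns `oligo_name`, `direction` (`FW`/`RV`, may be
#' empty for adapters), `sequence`, `position`. A copy of the study's
#' amplification-oligo table ships with the package
#' (`system.file("extdata", "ljv_primers.tsv", package = "polymap")`).
#'
#' @param path TSV path.
#' @return Data frame of oligos.
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character())
  need <- c("oligo_name", "direction", "sequence")
  if (!all(need %in% names(tab)))
    stop("primer table must have columns ", paste(need, collapse = ", "))
  bad <- grepl("[^ACGTU]", toupper(tab$sequence))
  if (any(bad)) stop("non-nucleotide characters in oligo ",
                     tab$oligo_name[which(bad)[1L]])
  tab
}

#' Count genome-spanning amplicon primer pairs
#'
#' An amplicon pair is an oligo name for which both a forward (`FW`) and a
#' reverse (`RV`) primer are listed; RACE and adapter oligos do not pair.
#'
#' @param primers Data frame from [read_primer_table()].
#' @return Integer count of complete FW/RV pairs.
#' @export
count_amplicon_pairs <- function(primers) {
  has_fw <- unique(primers$oligo_name[primers$direction == "FW"])
  has_rv <- unique(primers$oligo_name[primers$direction == "RV"])
  length(intersect(has_fw, has_rv))
}
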