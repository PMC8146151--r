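# N-terminal (Edman) read localization on the polyprotein.

#' Edman N-terminal read
#'
#' A short N-terminal sequencing read (typically a decapeptide). 'X' marks a
#' cycle whose residue call failed; reads with more than 40% undetermined
#' cycles are rejected as uninformative.
#'
#' @param spot_id Identifier of the spot/band the read came from.
#' @param residues Residue string of length >= 5 over the 20 residues plus X.
#' @return Object of class `edman_read`.
#' @export
edman_read <- function(spot_id, residues) {
  residues <- toupper(residues)
  chars <- .check_residues(residues, allow_x = TRUE, what = "Edman read")
  if (length(chars) < 5L) stop("Edman read must have at least 5 residues")
  if (sum(chars == "X") > 0.4 * length(chars))
    stop("Edman read has more than 40% undetermined (X) cycles")
  structure(list(spot_id = as.character(spot_id), residues = residues),
            class = "edman_read")
}

#' Read Edman reads from a TSV (spot_id, sequence)
#'
#' @param path TSV path with columns `spot_id` and `sequence`.
#' @return List of [edman_read()] objects.
#' @export
read_edman_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("spot_id", "sequence") %in% names(tab)))
    stop("Edman read file must have columns spot_id and sequence: ", path)
  lapply(seq_len(nrow(tab)),
         function(i) edman_read(tab$spot_id[i], tab$sequence[i]))
}

#' Locate an Edman read on a polyprotein
#'
#' Finds every start position where the read matches the polyprotein with at
#' most `max_mismatches` substitutions; an 'X' cycle matches any residue at
#' zero cost. Each anchor implies a cleavage immediately before the read
#' (cleavage after `start - 1`; 0 means the polyprotein N-terminus itself).
#'
#' @param read An [edman_read()].
#' @param polyprotein A [polyprotein_record()].
#' @param max_mismatches Maximum substitutions tolerated (default 1).
#' @return Data frame with columns `spot_id`, `start`,
#'   `implied_cleavage_after`, `mismatches`, sorted by (mismatches, start).
#' @export
locate_read <- function(read, polyprotein, max_mismatches = 1L) {
  stopifnot(inherits(read, "edman_read"),
            inherits(polyprotein, "polyprotein_record"),
            max_mismatches >= 0L)
  r <- .seq_chars(read$residues)
  p <- .seq_chars(polyprotein$sequence)
  L <- length(r)
  n <- length(p)
  if (L > n) {
    return(data.frame(spot_id = character(), start = integer(),
                      implied_cleavage_after = integer(),
                      mismatches = integer()))
  }
  n_pos <- n - L + 1L
  mism <- integer(n_pos)
  for (k in seq_len(L)) {
    if (r[k] == "X") next
    mism <- mism + (p[k:(k + n_pos - 1L)] != r[k])
  }
  hits <- which(mism <= max_mismatches)
  out <- data.frame(spot_id = rep(read$spot_id, length(hits)),
                    start = hits,
                    implied_cleavage_after = hits - 1L,
                    mismatches = mism[hits],
                    stringsAsFactors = FALSE)
  out[order(out$mismatches, out$start), , drop = FALSE]
}

#' Locate a set of Edman reads and flag ambiguous anchors
#'
#' Applies [locate_read()] to each read and keeps, per read, the best hits
#' (fewest mismatches). Reads with several equally good hits are flagged
#' ambiguous; map assembly ignores ambiguous anchors.
#'
#' @param reads List of [edman_read()] objects.
#' @param polyprotein A [polyprotein_record()].
#' @param max_mismatches Maximum substitutions tolerated per read.
#' @return Data frame of anchors with columns `spot_id`, `start`,
#'   `implied_cleavage_after`, `mismatches`, `ambiguous`.
#' @export
locate_reads <- function(reads, polyprotein, max_mismatches = 1L) {
  rows <- lapply(reads, function(rd) {
    hits <- locate_read(rd, polyprotein, max_mismatches)
    if (nrow(hits) == 0L) return(NULL)
    best <- hits[hits$mismatches == hits$mismatches[1L], , drop = FALSE]
    best$ambiguous <- nrow(best) > 1L
    best
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(spot_id = character(), start = integer(),
                      implied_cleavage_after = integer(),
                      mismatches = integer(), ambiguous = logical()))
  }
  do.call(rbind, rows)
}
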