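# In silico proteolytic digestion with coordinate tracking.

.protein_seq <- function(protein) {
  if (inherits(protein, "polyprotein_record")) protein$sequence
  else if (is.character(protein) && length(protein) == 1L) toupper(protein)
  else stop("protein must be a polyprotein_record or a character scalar")
}

.protein_id <- function(protein) {
  if (inherits(protein, "polyprotein_record")) protein$id else "protein"
}

# 1-based positions i such that trypsin cuts after residue i:
# after K or R, except when the next residue is P (unless the rule is off).
.tryptic_cut_points <- function(chars, not_before_proline = TRUE) {
  n <- length(chars)
  if (n < 2L) return(integer())
  i <- which(chars[-n] %in% c("K", "R"))
  if (not_before_proline) i <- i[chars[i + 1L] != "P"]
  i
}

#' Tryptic digest with missed cleavages
#'
#' Cleaves after K or R except before P (the classical trypsin rule; the
#' proline exception can be disabled) and returns every peptide carrying 0 to
#' `max_missed` internal missed cleavage sites. Zero-missed peptides tile the
#' parent exactly.
#'
#' @param protein A [polyprotein_record()] or amino-acid string.
#' @param max_missed Maximum internal missed cleavage sites (default 1).
#' @param not_before_proline Apply the "no cleavage before proline" exception
#'   (default `TRUE`).
#' @return Data frame with columns `parent_id`, `start`, `end`, `seq`,
#'   `missed_cleavages`, `cterm_is_protein_cterm`.
#' @examples
#' tryptic_digest("AKRP", max_missed = 0)  # "AK", "RP"
#' @export
tryptic_digest <- function(protein, max_missed = 1L,
                           not_before_proline = TRUE) {
  stopifnot(max_missed >= 0L)
  seq <- .protein_seq(protein)
  chars <- .check_residues(seq, what = "protein")
  n <- length(chars)
  cuts <- .tryptic_cut_points(chars, not_before_proline)
  bounds <- c(0L, cuts, n)              # fragment k spans bounds[k]+1..bounds[k+1]
  nfrag <- length(bounds) - 1L
  rows <- vector("list", max_missed + 1L)
  for (m in 0:max_missed) {
    if (m + 1L > nfrag) break
    first <- seq_len(nfrag - m)
    starts <- bounds[first] + 1L
    ends <- bounds[first + m + 1L]
    rows[[m + 1L]] <- data.frame(
      parent_id = .protein_id(protein),
      start = starts, end = ends,
      seq = substring(seq, starts, ends),
      missed_cleavages = m,
      cterm_is_protein_cterm = ends == n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Semitryptic peptides ending at the protein C-terminus
#'
#' Peptides whose C-terminus is the protein C-terminus and whose N-terminus
#' is the protein N-terminus or any tryptic cut point. These capture mature-
#' protein C-terminal peptides that trypsin alone could not generate, e.g.
#' the C-terminal peptide that closes a structural-protein region.
#'
#' @inheritParams tryptic_digest
#' @return Data frame in the same layout as [tryptic_digest()], all rows
#'   flagged `cterm_is_protein_cterm`.
#' @export
semitryptic_cterm_peptides <- function(protein, max_missed = 1L,
                                       not_before_proline = TRUE) {
  stopifnot(max_missed >= 0L)
  seq <- .protein_seq(protein)
  chars <- .check_residues(seq, what = "protein")
  n <- length(chars)
  cuts <- .tryptic_cut_points(chars, not_before_proline)
  starts <- c(1L, cuts + 1L)
  starts <- starts[starts <= n]
  missed <- vapply(starts, function(s) sum(cuts >= s & cuts < n), integer(1))
  keep <- missed <= max_missed
  data.frame(
    parent_id = .protein_id(protein),
    start = starts[keep], end = n,
    seq = substring(seq, starts[keep], n),
    missed_cleavages = missed[keep],
    cterm_is_protein_cterm = TRUE,
    stringsAsFactors = FALSE)
}
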