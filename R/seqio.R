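# Sequence input/output, ORF finding and translation, genome statistics.
#
# Coordinates are 1-based and inclusive throughout. Nucleotide sequences are
# normalized internally to the DNA alphabet (U -> T); reporting functions
# print composition in RNA terms because genomes of positive-sense RNA
# viruses are conventionally described with U.

#' Genome record
#'
#' @param id Identifier string.
#' @param sequence Nucleotide string over A/C/G/T/U (U is normalized to T).
#' @param description Optional free-text description.
#' @return Object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  if (!nzchar(sequence)) stop("genome sequence must be non-empty")
  if (grepl("[^ACGT]", sequence)) {
    bad <- regmatches(sequence, regexpr("[^ACGT]", sequence))
    stop("invalid nucleotide '", bad, "' in genome record '", id, "'")
  }
  structure(list(id = id, sequence = sequence, description = description),
            class = "genome_record")
}

#' Polyprotein record
#'
#' @param id Identifier string.
#' @param sequence Amino-acid string over the 20 standard residues (no stop
#'   symbol).
#' @param source_orf Optional [orf_annotation()] locating the coding region
#'   on the genome.
#' @return Object of class `polyprotein_record`.
#' @export
polyprotein_record <- function(id, sequence, source_orf = NULL) {
  sequence <- toupper(sequence)
  .check_residues(sequence, what = paste0("polyprotein '", id, "'"))
  structure(list(id = id, sequence = sequence, length = nchar(sequence),
                 source_orf = source_orf),
            class = "polyprotein_record")
}

#' ORF annotation
#'
#' @param start 1-based position of the first base of the start codon.
#' @param end 1-based position of the last base of the stop codon (inclusive).
#' @param frame Reading frame 0-2 (`(start - 1) %% 3`).
#' @return Object of class `orf_annotation`.
#' @export
orf_annotation <- function(start, end, frame = (start - 1L) %% 3L) {
  stopifnot(start >= 1L, end > start, (end - start + 1L) %% 3L == 0L)
  structure(list(start = as.integer(start), end = as.integer(end),
                 frame = as.integer(frame)),
            class = "orf_annotation")
}

.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.looks_like_nt <- function(s) !grepl("[^ACGTU]", toupper(s))

#' Read sequence records from FASTA or GenBank flat files
#'
#' Returns genome records for nucleotide entries and polyprotein records for
#' amino-acid entries, detected from the sequence alphabet. Identifiers are
#' preserved verbatim.
#'
#' @param path File path.
#' @param format `"fasta"` or `"genbank"`.
#' @return List of [genome_record()] / [polyprotein_record()] objects (empty
#'   list for an empty file).
#' @export
read_sequences <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    if (!any(grepl("^>", lines))) {
      if (all(!nzchar(trimws(lines)))) return(list())
      stop("malformed FASTA (no header lines): ", path)
    }
    set <- Biostrings::readBStringSet(path)
    out <- vector("list", length(set))
    for (i in seq_along(set)) {
      header <- names(set)[i]
      id <- sub("\\s.*$", "", header)
      desc <- sub("^\\S+\\s*", "", header)
      s <- as.character(set[[i]])
      if (!nzchar(s)) stop("malformed record (empty sequence): ", id)
      out[[i]] <- if (.looks_like_nt(s)) {
        genome_record(id, s, desc)
      } else {
        polyprotein_record(id, s)
      }
    }
    return(out)
  }
  .read_genbank(path)
}

# Minimal GenBank flat-file reader: LOCUS name, DEFINITION, ORIGIN sequence.
# (No offline GenBank flat-file parser exists among the installed packages.)
.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list())
  rec_end <- grep("^//", lines)
  if (length(rec_end) == 0L) stop("malformed GenBank file (no // terminator): ",
                                  path)
  rec_start <- c(1L, utils::head(rec_end, -1L) + 1L)
  out <- list()
  for (k in seq_along(rec_end)) {
    block <- lines[rec_start[k]:rec_end[k]]
    locus <- grep("^LOCUS", block, value = TRUE)
    if (length(locus) == 0L) next
    id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
    defn <- grep("^DEFINITION", block, value = TRUE)
    desc <- if (length(defn)) trimws(sub("^DEFINITION", "", defn[1L])) else ""
    org <- grep("^ORIGIN", block)
    if (length(org) == 0L) stop("malformed GenBank record '", id,
                                "': no ORIGIN section")
    seq_lines <- block[(org[1L] + 1L):(length(block) - 1L)]
    s <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))
    out[[length(out) + 1L]] <- if (.looks_like_nt(s)) {
      genome_record(id, s, desc)
    } else {
      polyprotein_record(id, s)
    }
  }
  out
}

#' Write records to a FASTA file
#'
#' @param records List of genome/polyprotein records.
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id,
                      if (nzchar(r$description %||% "")) paste0(" ", r$description) else ""),
               con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest forward-strand ORF
#'
#' Scans the three forward reading frames (positive-sense RNA virus
#' convention) for ATG-to-stop open reading frames and returns the longest
#' one with at least `min_aa` codons before the stop. Ties are broken by the
#' smallest start position. With `six_frame = TRUE` the reverse complement
#' is scanned as well and reverse hits are reported on plus-strand
#' coordinates with `strand = "-"`.
#'
#' @param genome A [genome_record()].
#' @param min_aa Minimum number of codons before the stop codon.
#' @param six_frame Also scan the reverse complement (default `FALSE`).
#' @return An [orf_annotation()].
#' @export
find_longest_orf <- function(genome, min_aa = 100L, six_frame = FALSE) {
  stopifnot(inherits(genome, "genome_record"), min_aa >= 1L)
  best <- .scan_orfs(genome$sequence, min_aa)
  if (six_frame) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(genome$sequence)))
    best_rc <- .scan_orfs(rc, min_aa)
    if (!is.null(best_rc) &&
        (is.null(best) || best_rc$n_codons > best$n_codons)) {
      n <- nchar(genome$sequence)
      ann <- orf_annotation(n - best_rc$end + 1L, n - best_rc$start + 1L,
                            frame = (best_rc$start - 1L) %% 3L)
      ann$strand <- "-"
      return(ann)
    }
  }
  if (is.null(best)) {
    stop("no ORF with at least ", min_aa, " codons found in '",
         genome$id, "'")
  }
  ann <- orf_annotation(best$start, best$end)
  ann$strand <- "+"
  ann
}

.scan_orfs <- function(seq, min_aa) {
  n <- nchar(seq)
  chars <- .seq_chars(seq)
  best <- NULL
  for (frame in 0:2) {
    starts <- seq(frame + 1L, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)
    for (ai in which(is_atg)) {
      nxt <- stop_idx[stop_idx > ai]
      if (length(nxt) == 0L) next
      sc <- nxt[1L]
      n_codons <- sc - ai
      if (n_codons < min_aa) next
      if (is.null(best) || n_codons > best$n_codons ||
          (n_codons == best$n_codons && starts[ai] < best$start)) {
        best <- list(start = starts[ai], end = starts[sc] + 2L,
                     n_codons = n_codons)
      }
    }
  }
  best
}

#' Translate an ORF to a polyprotein record
#'
#' Standard genetic code; the terminal stop is removed. An internal stop
#' codon is an error (it would indicate a mis-annotated ORF).
#'
#' @param genome A [genome_record()].
#' @param orf An [orf_annotation()] valid for `genome`.
#' @return A [polyprotein_record()] with `source_orf` set.
#' @export
translate_orf <- function(genome, orf) {
  stopifnot(inherits(genome, "genome_record"), inherits(orf, "orf_annotation"))
  if (orf$end > nchar(genome$sequence)) stop("ORF extends past genome end")
  cds <- substr(genome$sequence, orf$start, orf$end)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  n <- nchar(aa)
  if (substr(aa, n, n) != "*") stop("ORF does not end in a stop codon")
  body <- substr(aa, 1L, n - 1L)
  internal <- regexpr("*", body, fixed = TRUE)
  if (internal > 0L) {
    stop("internal stop codon at codon index ", internal,
         " of ORF in '", genome$id, "'")
  }
  polyprotein_record(genome$id, body, source_orf = orf)
}

#' Genome descriptive statistics
#'
#' Genome length, UTR lengths implied by the ORF, and base composition.
#' Composition is reported in RNA terms (U for T) and sums to one. With
#' `exclude_polya_tail` a maximal terminal run of 10 or more A's is excluded
#' from both the length and the fractions, matching the convention of
#' describing polyadenylated genomes "excluding the poly(A) tail".
#'
#' @param genome A [genome_record()].
#' @param orf An [orf_annotation()].
#' @param exclude_polya_tail Exclude a terminal poly(A) run (>= 10 A's).
#' @return List with `length`, `utr5_len`, `utr3_len`, `base_fractions`
#'   (named A/C/G/U), and `polya_len` (number of excluded tail bases).
#' @export
genome_stats <- function(genome, orf, exclude_polya_tail = FALSE) {
  stopifnot(inherits(genome, "genome_record"), inherits(orf, "orf_annotation"))
  s <- genome$sequence
  polya_len <- 0L
  if (exclude_polya_tail) {
    m <- regexpr("A{10,}$", s)
    if (m > 0L) {
      polya_len <- attr(m, "match.length")
      s <- substr(s, 1L, nchar(s) - polya_len)
    }
  }
  n <- nchar(s)
  if (orf$end > n) stop("ORF extends into the excluded poly(A) tail")
  chars <- .seq_chars(s)
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), U = sum(chars == "T"))
  fr <- counts / n
  stopifnot(abs(sum(fr) - 1) < 1e-9)
  list(length = n,
       utr5_len = orf$start - 1L,
       utr3_len = n - orf$end,
       base_fractions = fr,
       polya_len = polya_len)
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$id, "-", nchar(x$sequence), "nt\n")
  invisible(x)
}

#' @export
print.polyprotein_record <- function(x, ...) {
  cat("<polyprotein_record>", x$id, "-", x$length, "aa\n")
  invisible(x)
}
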