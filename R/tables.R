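#' @keywords internal
"_PACKAGE"

# Package-local cache for the plain-text constant tables shipped in extdata.
.polymap_env <- new.env(parent = emptyenv())

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Water and proton masses (Da). Monoisotopic/average water; proton for
# converting singly protonated m/z lists to neutral masses.
WATER_MONO <- 18.010565
WATER_AVG  <- 18.015286
PROTON_MASS <- 1.007276

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "polymap")
  if (!nzchar(path)) stop("bundled data file not found: ", name)
  path
}

#' Residue mass table
#'
#' Per-residue monoisotopic and average masses (Da) for the 20 standard
#' amino acids, loaded from the package's plain-text table.
#'
#' @return Data frame with columns `residue`, `monoisotopic`, `average`.
#' @export
residue_masses <- function() {
  if (is.null(.polymap_env$residue_masses)) {
    tab <- utils::read.delim(.extdata("residue_masses.tsv"),
                             stringsAsFactors = FALSE)
    stopifnot(all(AA20 %in% tab$residue), all(tab$monoisotopic > 0),
              all(tab$average > 0))
    .polymap_env$residue_masses <- tab
  }
  .polymap_env$residue_masses
}

#' Modification delta table
#'
#' Mass shifts for supported residue modifications: carbamidomethylation of
#' cysteine (alkylation during sample preparation, treated as fixed) and
#' oxidation of methionine (variable).
#'
#' @return Data frame with columns `modification`, `target`, `monoisotopic`,
#'   `average`.
#' @export
modification_deltas <- function() {
  if (is.null(.polymap_env$mod_deltas)) {
    tab <- utils::read.delim(.extdata("modification_deltas.tsv"),
                             stringsAsFactors = FALSE)
    stopifnot(all(tab$target %in% AA20))
    .polymap_env$mod_deltas <- tab
  }
  .polymap_env$mod_deltas
}

#' pKa table for isoelectric-point calculation
#'
#' Returns the pKa values (N-terminus, C-terminus and the ionizable side
#' chains C, D, E, H, K, R, Y) for a named published set. Tables are shipped
#' as data so alternative sets reproduce other tools' pI values.
#'
#' @param set Name of the pKa set; `"bjellqvist"` (default) or `"emboss"`.
#' @return Named numeric vector of pKa values.
#' @export
pka_table <- function(set = "bjellqvist") {
  if (is.null(.polymap_env$pka_all)) {
    .polymap_env$pka_all <- utils::read.delim(.extdata("pka_tables.tsv"),
                                              stringsAsFactors = FALSE)
  }
  tab <- .polymap_env$pka_all
  rows <- tab[tab$set == set, ]
  if (nrow(rows) == 0L) {
    stop("unknown pKa set '", set, "'; available: ",
         paste(unique(tab$set), collapse = ", "))
  }
  pka <- stats::setNames(rows$pka, rows$group)
  stopifnot(all(pka > 0 & pka < 14))
  pka
}

# residue validation shared by several modules
.check_residues <- function(seq, allow_x = FALSE, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || !nzchar(seq))
    stop(what, " must be a non-empty character scalar")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- chars %in% AA20 | (allow_x & chars == "X")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("invalid residue '", chars[bad], "' at position ", bad,
         " in ", what)
  }
  chars
}
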