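# Positional scanning for protease cleavage-site motifs.
#
# The 3C-like proteases of picorna-like viruses cleave immediately after
# glutamine or glutamic acid (P1), here with methionine preferred at P1'.
# Flanking preferences (P/A at -4, acidic residues at +2/+3) are scored as
# additive integer bonuses on top of a mandatory core. The additive scheme
# and its default weights are this package's formalization of a qualitative
# motif description; they live in data (a key-value model) so alternative
# weightings are configuration changes, not code changes.
#
# Offset convention: P1 is offset -1 (the residue N-terminal of the scissile
# bond), P1' is offset +1. A bonus at offset -4 refers to the P4 residue.

#' Cleavage motif model
#'
#' @param name Model name.
#' @param p1_residues Allowed P1 residues (immediately N-terminal of the
#'   scissile bond); default Q and E.
#' @param p1prime_residues Allowed P1' residues; default M.
#' @param bonus_features List of `list(offset, residues, weight)` entries;
#'   offsets in -4..+4 excluding the -1/+1 core.
#' @param core_weight Score contributed by a satisfied core (default 2).
#' @param min_score Minimum score for a site to be reported (default 2, i.e.
#'   the core alone qualifies).
#' @return Object of class `cleavage_motif_model`.
#' @export
cleavage_motif_model <- function(name = "q_m_3c",
                                 p1_residues = c("Q", "E"),
                                 p1prime_residues = "M",
                                 bonus_features = list(
                                   list(offset = -4L, residues = c("P", "A"), weight = 1L),
                                   list(offset = 2L, residues = c("D", "E"), weight = 1L),
                                   list(offset = 3L, residues = c("D", "E"), weight = 1L)),
                                 core_weight = 2L, min_score = 2L) {
  for (b in bonus_features) {
    stopifnot(b$offset %in% c(-4:-2, 2:4), b$weight >= 0,
              all(b$residues %in% AA20))
  }
  stopifnot(all(p1_residues %in% AA20), all(p1prime_residues %in% AA20),
            core_weight >= 0, min_score >= 0)
  structure(list(name = name, p1_residues = p1_residues,
                 p1prime_residues = p1prime_residues,
                 bonus_features = bonus_features,
                 core_weight = as.integer(core_weight),
                 min_score = as.integer(min_score)),
            class = "cleavage_motif_model")
}

#' Divergent M/D cleavage model
#'
#' Some capsid-protein N-termini of picorna-like viruses are generated at an
#' M/D site rather than the canonical Q|E / M site, with a conserved proline
#' at +3 (e.g. an IKNM/DKPY context); this may reflect a second protease or
#' an atypical 3C specificity. Core M at P1 and D at P1', bonus P at +3.
#'
#' @return A [cleavage_motif_model()] named `"md_divergent"`.
#' @export
md_divergent_model <- function() {
  cleavage_motif_model(name = "md_divergent", p1_residues = "M",
                       p1prime_residues = "D",
                       bonus_features = list(
                         list(offset = 3L, residues = "P", weight = 1L)),
                       core_weight = 2L, min_score = 2L)
}

#' Read a motif model from a key-value text file
#'
#' Recognized keys: `name`, `p1`, `p1prime`, `core_weight`, `min_score`, and
#' repeated `bonus` entries of the form `offset:residues:weight`
#' (e.g. `bonus = -4:PA:1`). Residue sets are strings of one-letter codes.
#'
#' @param path Path to the key-value file.
#' @return A [cleavage_motif_model()].
#' @export
read_motif_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.+?)\\s*$", lines))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  getv <- function(k, default) if (k %in% keys) vals[keys == k][1L] else default
  bonuses <- lapply(vals[keys == "bonus"], function(v) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) stop("malformed bonus entry: ", v)
    list(offset = as.integer(parts[1L]),
         residues = .seq_chars(toupper(parts[2L])),
         weight = as.integer(parts[3L]))
  })
  cleavage_motif_model(
    name = getv("name", basename(path)),
    p1_residues = .seq_chars(toupper(getv("p1", "QE"))),
    p1prime_residues = .seq_chars(toupper(getv("p1prime", "M"))),
    bonus_features = bonuses,
    core_weight = as.integer(getv("core_weight", "2")),
    min_score = as.integer(getv("min_score", "2")))
}

#' Scan a polyprotein for candidate cleavage sites
#'
#' Scores every position i (cleavage after residue i) as
#' `core_weight * [res(i) in P1 and res(i+1) in P1']` plus the sum of the
#' satisfied bonus weights; the core is mandatory (score 0 without it).
#' Sites scoring at least `min_score` are returned sorted by position.
#' Sites within 5 residues of a terminus are flagged (truncated window).
#'
#' @param polyprotein A [polyprotein_record()] or amino-acid string.
#' @param model A [cleavage_motif_model()].
#' @param region Optional `c(from, to)` interval restricting the reported
#'   cleavage positions.
#' @return Data frame with columns `cleavage_after`, `window`, `score`,
#'   `model_name`, `near_terminus`.
#' @export
scan_cleavage_sites <- function(polyprotein, model = cleavage_motif_model(),
                                region = NULL) {
  seq <- .protein_seq(polyprotein)
  chars <- .check_residues(seq, what = "polyprotein")
  n <- length(chars)
  if (n < 2L) {
    return(data.frame(cleavage_after = integer(), window = character(),
                      score = integer(), max_score = integer(),
                      model_name = character(), near_terminus = logical()))
  }
  pos <- seq_len(n - 1L)
  core <- chars[pos] %in% model$p1_residues &
    chars[pos + 1L] %in% model$p1prime_residues
  score <- ifelse(core, model$core_weight, 0L)
  for (b in model$bonus_features) {
    # offset -k is residue i-k+1 (P1 = offset -1); offset +k is residue i+k
    at <- pos + ifelse(b$offset < 0L, b$offset + 1L, b$offset)
    ok <- at >= 1L & at <= n
    sat <- ok & core
    sat[ok] <- sat[ok] & chars[at[ok]] %in% b$residues
    score <- score + ifelse(sat, b$weight, 0L)
  }
  keep <- core & score >= model$min_score
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] >= 1L, region[2L] <= n)
    keep <- keep & pos >= region[1L] & pos <= region[2L]
  }
  hits <- pos[keep]
  if (length(hits) == 0L) {
    return(data.frame(cleavage_after = integer(), window = character(),
                      score = integer(), max_score = integer(),
                      model_name = character(), near_terminus = logical()))
  }
  max_score <- model$core_weight +
    sum(vapply(model$bonus_features, `[[`, numeric(1), "weight"))
  data.frame(
    cleavage_after = hits,
    window = substring(seq, pmax(hits - 3L, 1L), pmin(hits + 4L, n)),
    score = score[keep],
    max_score = max_score,
    model_name = model$name,
    near_terminus = hits <= 5L | hits >= n - 5L,
    stringsAsFactors = FALSE)
}

#' Scan for divergent M/D sites
#'
#' Convenience wrapper running [scan_cleavage_sites()] under the
#' [md_divergent_model()].
#'
#' @inheritParams scan_cleavage_sites
#' @return Data frame as in [scan_cleavage_sites()], `model_name`
#'   `"md_divergent"`.
#' @export
scan_divergent_md <- function(polyprotein, region = NULL) {
  scan_cleavage_sites(polyprotein, md_divergent_model(), region)
}
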