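# Evidence integration: assemble a cleavage map of the structural-protein
# region from Edman anchors, PMF coverage blocks, motif candidates, and
# apparent spot molecular weights.
#
# The assembly logic mirrors how such maps are built by hand: experimentally
# determined N-termini are fixed first; remaining boundaries are picked from
# motif candidates that no fingerprint coverage block straddles, preferring
# the candidate whose implied segment weight best matches the observed gel
# weight of the corresponding spot.

#' Evidence set for map assembly
#'
#' @param anchors Data frame of Edman anchors ([locate_reads()] output, or
#'   any table with `spot_id`, `start`, `implied_cleavage_after`,
#'   `ambiguous`).
#' @param pmf_results List of `pmf_result` objects whose coverage blocks are
#'   expressed in polyprotein coordinates (i.e. matched against the
#'   polyprotein).
#' @param candidate_sites Data frame of candidate sites
#'   ([scan_cleavage_sites()] output).
#' @param spot_observations Optional data frame with `spot_id`,
#'   `apparent_mw_kda` and optionally `apparent_pi`.
#' @param region_end 1-based residue position closing the structural region
#'   (the final cleavage position).
#' @param fixed_positions Optional integer vector of known cleavage-after
#'   positions to impose directly (e.g. published boundaries); treated like
#'   unambiguous anchors with no spot attached.
#' @return Object of class `evidence_set`.
#' @export
evidence_set <- function(anchors = NULL, pmf_results = list(),
                         candidate_sites = NULL, spot_observations = NULL,
                         region_end, fixed_positions = integer()) {
  stopifnot(is.numeric(region_end), length(region_end) == 1L, region_end >= 1)
  if (is.null(anchors)) {
    anchors <- data.frame(spot_id = character(), start = integer(),
                          implied_cleavage_after = integer(),
                          mismatches = integer(), ambiguous = logical())
  }
  if (is.null(candidate_sites)) {
    candidate_sites <- data.frame(cleavage_after = integer(),
                                  window = character(), score = integer(),
                                  model_name = character(),
                                  near_terminus = logical())
  }
  structure(list(anchors = anchors, pmf_results = pmf_results,
                 candidate_sites = candidate_sites,
                 spot_observations = spot_observations,
                 region_end = as.integer(region_end),
                 fixed_positions = as.integer(fixed_positions)),
            class = "evidence_set")
}

.all_coverage_blocks <- function(pmf_results) {
  blocks <- lapply(pmf_results, function(r) r$coverage_blocks)
  blocks <- blocks[vapply(blocks, nrow, integer(1)) > 0L]
  if (length(blocks) == 0L) return(data.frame(start = integer(), end = integer()))
  do.call(rbind, blocks)
}

# A cleavage position b is treated as straddled by fingerprint evidence only
# when, within a single spot, at least `min_support` independent matched
# peptide intervals cover both b and b+1. Single matched peptides at a 75 ppm
# tolerance are frequently chance mass coincidences, and even two overlapping
# ones co-occur often enough across a long polyprotein that they cannot be
# allowed to override direct evidence; three independent peptides of one
# protein spanning the same position are solid evidence that the protein is
# not cleaved there.
.straddled <- function(positions, pmf_results, min_support = 3L) {
  if (length(positions) == 0L) return(logical(0))
  per_spot <- lapply(pmf_results, function(r) {
    m <- r$matches
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    unique(m[, c("start", "end", "peak_idx")])
  })
  per_spot <- per_spot[!vapply(per_spot, is.null, logical(1))]
  vapply(positions, function(b) {
    any(vapply(per_spot, function(iv) {
      s <- unique(iv[iv$start <= b & iv$end > b, , drop = FALSE])
      # support = distinct straddling intervals backed by distinct peaks;
      # genuine coverage of an uncleaved position yields the zero-missed
      # peptide plus both of its missed-cleavage extensions (3 intervals,
      # 3 peaks), whereas chance coincidences rarely exceed 2
      min(nrow(unique(s[, c("start", "end")])),
          length(unique(s$peak_idx))) >= min_support
    }, logical(1)))
  }, logical(1))
}

#' Assemble a cleavage map from evidence
#'
#' Procedure: (1) fix boundaries at unambiguous Edman anchors (and any
#' imposed positions); (2) in each gap between fixed points, consider
#' candidate motif sites that no PMF coverage block straddles; (3) among the
#' survivors pick the boundary whose implied segment weight best matches the
#' observed spot weight when one is attached to the gap's N-terminal segment
#' -- leaving the gap uncut is a competing hypothesis, so a gap is only split
#' when some cut fits the observed weight better than no cut; without a
#' weight observation only candidates showing the fully conserved motif
#' context (maximum attainable model score) qualify, the highest-scoring
#' 5'-most one winning; (4) close the region at `region_end`; (5) name the
#' N-terminal pre-anchor segment L and rank the remaining capsid segments by
#' descending calculated weight (largest = VP1, then VP3, VP2, VP4 for the
#' canonical four-capsid layout); (6) attach calculated MW/pI and evidence
#' tags. A gap with no qualifying candidate stays a merged segment with a
#' flagged note; a boundary is never invented.
#'
#' @param polyprotein A [polyprotein_record()].
#' @param evidence An [evidence_set()].
#' @return Object of class `cleavage_map` with elements `polyprotein_id`,
#'   `proteins` (data frame: name, start, end, calc_mw_kda, calc_pi,
#'   evidence), `boundaries`, `notes`.
#' @export
assemble_map <- function(polyprotein, evidence) {
  stopifnot(inherits(polyprotein, "polyprotein_record"),
            inherits(evidence, "evidence_set"))
  region_end <- evidence$region_end
  if (region_end > polyprotein$length)
    stop("region_end (", region_end, ") exceeds polyprotein length (",
         polyprotein$length, ")")
  anch <- evidence$anchors
  usable <- anch[!isTRUE_vec(anch$ambiguous) & anch$implied_cleavage_after > 0L &
                   anch$implied_cleavage_after < region_end, , drop = FALSE]
  fixed <- sort(unique(c(usable$implied_cleavage_after,
                         evidence$fixed_positions)))
  fixed <- fixed[fixed > 0L & fixed < region_end]

  # contradiction: an anchor-implied cleavage inside supported fingerprint
  # coverage means peptides of one spot's protein span the supposed boundary
  conflict <- fixed[.straddled(fixed, evidence$pmf_results)]
  if (length(conflict) > 0L) {
    stop("contradictory evidence: coverage blocks straddle anchored ",
         "cleavage position(s) ", paste(conflict, collapse = ", "))
  }

  notes <- character()
  if (any(isTRUE_vec(anch$ambiguous))) {
    notes <- c(notes, paste0("ambiguous anchors ignored for spots: ",
                             paste(unique(anch$spot_id[isTRUE_vec(anch$ambiguous)]),
                                   collapse = ", ")))
  }

  cand <- evidence$candidate_sites
  cand <- cand[cand$cleavage_after < region_end, , drop = FALSE]
  cand <- cand[!.straddled(cand$cleavage_after, evidence$pmf_results), ,
               drop = FALSE]

  boundaries <- fixed
  chosen_info <- list()
  gap_bounds <- c(0L, fixed, region_end)
  for (g in seq_len(length(gap_bounds) - 1L)) {
    lo <- gap_bounds[g]
    hi <- gap_bounds[g + 1L]
    if (hi - lo <= 1L) next
    inside <- cand[cand$cleavage_after > lo & cand$cleavage_after < hi, ,
                   drop = FALSE]
    inside <- inside[!inside$cleavage_after %in% fixed, , drop = FALSE]
    if (nrow(inside) == 0L) next   # no evidence of further cleavage here
    pick <- .pick_boundary(polyprotein, inside, lo, hi, usable,
                           evidence$spot_observations)
    if (is.null(pick)) {
      notes <- c(notes, paste0("no candidate preferred over the uncut segment in gap (",
                               lo, ", ", hi, "]; segment kept merged"))
      next
    }
    boundaries <- sort(c(boundaries, pick$position))
    chosen_info[[as.character(pick$position)]] <- pick
  }

  bnds <- sort(unique(boundaries))
  starts <- c(1L, bnds + 1L)
  ends <- c(bnds, region_end)
  n_seg <- length(starts)
  if (length(chosen_info) == 0L && length(fixed) == 0L && n_seg == 1L) {
    notes <- c(notes, "no internal boundary could be resolved; region kept as a single segment")
  }

  seqs <- substring(polyprotein$sequence, starts, ends)
  mw <- vapply(seqs, protein_average_mw, numeric(1))
  pi <- vapply(seqs, isoelectric_point, numeric(1))

  ev <- .evidence_tags(starts, ends, bnds, usable, evidence$pmf_results,
                       chosen_info, region_end)
  names_vec <- .name_segments(mw)

  proteins <- data.frame(name = names_vec, start = starts, end = ends,
                         calc_mw_kda = unname(mw), calc_pi = unname(pi),
                         evidence = ev, stringsAsFactors = FALSE)
  # unresolved-gap note: a segment containing an unpicked candidate-free gap
  structure(list(polyprotein_id = polyprotein$id,
                 proteins = proteins,
                 boundaries = bnds,
                 region_end = region_end,
                 notes = notes),
            class = "cleavage_map")
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else x %in% TRUE

# Choose at most one boundary for the gap (lo, hi); NULL means the gap is
# better explained without an additional cut.
.pick_boundary <- function(polyprotein, inside, lo, hi, anchors, spot_obs) {
  target_mw <- NA_real_
  if (!is.null(spot_obs) && nrow(anchors) > 0L) {
    # spot observation tied to the segment starting right after `lo`
    spots <- anchors$spot_id[anchors$start == lo + 1L]
    obs <- spot_obs$apparent_mw_kda[spot_obs$spot_id %in% spots]
    if (length(obs) > 0L) target_mw <- max(obs)  # largest form = pro-protein
  }
  if (!is.na(target_mw)) {
    chars <- .seq_chars(polyprotein$sequence)
    ends <- c(inside$cleavage_after, hi)   # hi = the uncut-gap hypothesis
    mw <- .interval_masses(chars, rep(lo + 1L, length(ends)), ends,
                           mode = "average", carbamidomethyl = FALSE) / 1000
    dev <- abs(mw - target_mw)
    best <- which(dev == min(dev))
    if (length(best) > 1L) {
      sc <- c(inside$score, Inf)[best]     # prefer the uncut hypothesis on ties
      best <- best[sc == max(sc)]
      best <- best[which.min(ends[best])]
    }
    if (best == length(ends)) return(NULL)
    return(list(position = inside$cleavage_after[best],
                used_mw = TRUE, score = inside$score[best]))
  }
  # Motif-only selection: require the fully conserved context, and only
  # trust the canonical protease model -- divergent-site models (e.g. M/D)
  # describe cleavages that are only credible with direct experimental
  # support such as an Edman anchor or a matching spot weight.
  if (!is.null(inside$model_name))
    inside <- inside[inside$model_name != "md_divergent", , drop = FALSE]
  if (nrow(inside) == 0L) return(NULL)
  full_bar <- if (!is.null(inside$max_score)) inside$max_score
              else max(inside$score)
  full <- inside[inside$score >= full_bar, , drop = FALSE]
  if (nrow(full) == 0L) return(NULL)
  best <- which(full$score == max(full$score))
  best <- best[which.min(full$cleavage_after[best])]
  list(position = full$cleavage_after[best], used_mw = FALSE,
       score = full$score[best])
}

.evidence_tags <- function(starts, ends, bnds, anchors, pmf_results,
                           chosen_info, region_end) {
  blocks <- .all_coverage_blocks(pmf_results)
  vapply(seq_along(starts), function(k) {
    tags <- character()
    if (starts[k] %in% (anchors$start)) tags <- c(tags, "edman_nterm")
    if (nrow(blocks) > 0L &&
        any(blocks$start <= ends[k] & blocks$end >= starts[k]))
      tags <- c(tags, "pmf_block")
    info <- chosen_info[[as.character(ends[k])]]
    if (!is.null(info)) {
      tags <- c(tags, "motif")
      if (info$used_mw) tags <- c(tags, "mass_constraint")
    }
    if (k == 1L || ends[k] == region_end) tags <- c(tags, "terminus")
    paste(tags, collapse = ";")
  }, character(1))
}

# Capsid naming by the traditional weight-ranking convention. For the
# canonical 5-segment layout (leader + 4 capsid segments) the rank order
# largest-to-smallest maps to VP1, VP3, VP2, VP4 so that gene order reads
# L-VP2-VP4-VP1-VP3; for other counts the capsid segments are named VP1..VPk
# by descending weight.
.name_segments <- function(mw) {
  n <- length(mw)
  if (n == 1L) return("P1")
  nm <- character(n)
  nm[1L] <- "L"
  capsid <- 2:n
  rk <- rank(-mw[capsid], ties.method = "first")
  if (length(capsid) == 4L) {
    rank_names <- c("VP1", "VP3", "VP2", "VP4")
  } else {
    rank_names <- paste0("VP", seq_along(capsid))
  }
  nm[capsid] <- rank_names[rk]
  nm
}

#' Infer a secondary internal processing site
#'
#' When two or more spots share an identical N-terminal anchor but differ in
#' apparent molecular weight, the smaller form likely arises from an internal
#' cleavage of the larger pro-protein. The position whose N-terminal fragment
#' calculated weight best matches the smaller observed weight is proposed as
#' a hypothesis (never a map boundary), along with which coverage blocks fall
#' on either side of it.
#'
#' @param polyprotein A [polyprotein_record()].
#' @param pro_start,pro_end Boundaries of the pro-protein segment.
#' @param anchors Anchor data frame ([locate_reads()] output).
#' @param spot_observations Data frame with `spot_id`, `apparent_mw_kda`.
#' @param pmf_results List of `pmf_result` objects (polyprotein coordinates).
#' @return `NULL` when the preconditions are not met, otherwise a list with
#'   `position`, `calc_nterm_mw_kda`, `target_mw_kda`, `blocks_nterm`,
#'   `blocks_cterm`, and `hypothesis = TRUE`.
#' @export
infer_internal_processing <- function(polyprotein, pro_start, pro_end,
                                      anchors, spot_observations,
                                      pmf_results = list()) {
  if (is.null(spot_observations) || nrow(anchors) == 0L) return(NULL)
  at_start <- anchors[anchors$start == pro_start, , drop = FALSE]
  obs <- spot_observations[spot_observations$spot_id %in% at_start$spot_id, ,
                           drop = FALSE]
  if (nrow(obs) < 2L) return(NULL)
  mws <- sort(unique(obs$apparent_mw_kda))
  if (length(mws) < 2L) return(NULL)
  target <- mws[1L]
  chars <- .seq_chars(polyprotein$sequence)
  cut_pos <- pro_start:(pro_end - 1L)
  frag_mw <- .interval_masses(chars, rep(pro_start, length(cut_pos)), cut_pos,
                              mode = "average", carbamidomethyl = FALSE) / 1000
  k <- which.min(abs(frag_mw - target))
  pos <- cut_pos[k]
  blocks <- .all_coverage_blocks(pmf_results)
  blocks <- blocks[blocks$start >= pro_start & blocks$end <= pro_end, ,
                   drop = FALSE]
  list(position = pos,
       calc_nterm_mw_kda = frag_mw[k],
       target_mw_kda = target,
       blocks_nterm = blocks[blocks$end <= pos, , drop = FALSE],
       blocks_cterm = blocks[blocks$start > pos, , drop = FALSE],
       hypothesis = TRUE)
}

#' @export
print.cleavage_map <- function(x, ...) {
  cat("Cleavage map of ", x$polyprotein_id, " - structural region 1..",
      x$region_end, "\n", sep = "")
  p <- x$proteins
  for (k in seq_len(nrow(p))) {
    cat(sprintf("  %-4s %5d-%5d  %6.1f kDa  pI %4.1f  [%s]\n",
                p$name[k], p$start[k], p$end[k], p$calc_mw_kda[k],
                p$calc_pi[k], p$evidence[k]))
  }
  if (length(x$notes)) cat("Notes:\n", paste0("  - ", x$notes, "\n"), sep = "")
  invisible(x)
}

#' @export
summary.cleavage_map <- function(object, ...) {
  cat(nrow(object$proteins), "mature proteins,",
      length(object$boundaries), "internal cleavage boundaries:",
      paste(object$boundaries, collapse = ", "), "\n")
  invisible(object$proteins)
}

#' @export
as.data.frame.cleavage_map <- function(x, ...) x$proteins

#' @export
plot.cleavage_map <- function(x, ...) {
  p <- x$proteins
  graphics::plot(NULL, xlim = c(0, x$region_end), ylim = c(0, 2),
                 xlab = "polyprotein residue", ylab = "", yaxt = "n",
                 main = paste("Cleavage map:", x$polyprotein_id), ...)
  cols <- grDevices::gray.colors(nrow(p), start = 0.4, end = 0.9)
  graphics::rect(p$start - 1, 0.5, p$end, 1.2, col = cols, border = "black")
  graphics::text((p$start + p$end) / 2, 0.85, p$name)
  graphics::text((p$start + p$end) / 2, 1.45,
                 sprintf("%.1f kDa", p$calc_mw_kda), cex = 0.8)
  invisible(x)
}

#' Write map reports (GFF3, TSV, JSON)
#'
#' Emits a `mat_peptide`-typed GFF3, a TSV summary and a JSON report for a
#' cleavage map. Output is deterministic for a fixed map. With a genome and
#' its ORF annotation, GFF3 features are written in genome (nucleotide)
#' coordinates; otherwise in protein coordinates. The coordinate mode is
#' stated in the GFF3 header.
#'
#' @param map A `cleavage_map`.
#' @param dir Output directory (created if missing).
#' @param genome Optional [genome_record()].
#' @param orf Optional [orf_annotation()]; required with `genome`.
#' @param prefix File-name prefix (default `"map"`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(map, dir, genome = NULL, orf = NULL, prefix = "map") {
  stopifnot(inherits(map, "cleavage_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- map$proteins
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  jsn <- file.path(dir, paste0(prefix, ".json"))

  genome_coords <- !is.null(genome)
  if (genome_coords && is.null(orf)) stop("genome coordinates require an ORF annotation")
  lines <- c("##gff-version 3",
             paste0("# coordinates: ",
                    if (genome_coords) "genome (nucleotide)" else "protein (residue)"))
  seqid <- if (genome_coords) genome$id else map$polyprotein_id
  for (k in seq_len(nrow(p))) {
    if (genome_coords) {
      s <- orf$start + 3L * (p$start[k] - 1L)
      e <- orf$start + 3L * p$end[k] - 1L
    } else {
      s <- p$start[k]; e <- p$end[k]
    }
    attrs <- sprintf("ID=%s;Name=%s;calc_mw_kda=%.1f;calc_pi=%.2f;evidence=%s",
                     p$name[k], p$name[k], p$calc_mw_kda[k], p$calc_pi[k],
                     p$evidence[k])
    lines <- c(lines, paste(seqid, "polymap", "mat_peptide", s, e, ".",
                            if (genome_coords) "+" else ".", ".", attrs,
                            sep = "\t"))
  }
  if (length(map$notes)) lines <- c(lines, paste0("# WARNING: ", map$notes))
  writeLines(lines, gff)

  out <- p
  out$calc_mw_kda <- round(out$calc_mw_kda, 1)
  out$calc_pi <- round(out$calc_pi, 2)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(
    list(polyprotein_id = map$polyprotein_id,
         region_end = map$region_end,
         boundaries = map$boundaries,
         proteins = p,
         notes = map$notes),
    jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(gff = gff, tsv = tsv, json = jsn))
}
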