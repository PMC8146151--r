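# Seeded synthetic-data generators: ground-truth cleavage maps with planted
# motif-conform boundary windows, back-translated genomes, Edman reads, PMF
# peak lists, and alignments evolved along a tree. All generators are pure
# functions of (parameters, seed).

CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), M = "ATG",
  N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))

#' Generate a ground-truth polyprotein, cleavage map and genome
#'
#' Draws segment lengths and interior residues from a background
#' distribution, writes every planted boundary window so that it satisfies
#' the motif core plus all bonus features, back-translates the polyprotein
#' with random synonymous codons, and flanks it with UTRs (and an optional
#' poly(A) tail). The defaults emulate an iflavirus layout: five structural
#' segments, a long nonstructural tail, and UTRs of 918/204 nt.
#'
#' @param n_segments Number of structural segments (>= 2; default 5).
#' @param length_range Segment length interval in residues (default 20-450).
#' @param segment_lengths Optional explicit segment lengths (overrides
#'   `n_segments`/`length_range`); e.g. `c(171, 237, 24, 424, 257)` with a
#'   1934-residue nonstructural tail reproduces an iflavirus-sized
#'   polyprotein of 3047 residues in a 10,266-nt genome.
#' @param motif A [cleavage_motif_model()] used for planting.
#' @param utr5,utr3 UTR lengths in nucleotides.
#' @param nonstructural_len Residues appended after the structural region
#'   (default 1934, giving realistically long polyproteins).
#' @param polya_len Poly(A)-tail length (default 0).
#' @param seed Integer seed; the truth is a pure function of it.
#' @return Object of class `synthetic_truth`: `polyprotein`, `genome`, `orf`,
#'   `boundaries` (true cleavage-after positions, including the region end),
#'   `segments` (data frame), `region_end`, `params`.
#' @export
generate_truth <- function(n_segments = 5L, length_range = c(20L, 450L),
                           segment_lengths = NULL,
                           motif = cleavage_motif_model(),
                           utr5 = 918L, utr3 = 204L,
                           nonstructural_len = 1934L, polya_len = 0L,
                           seed = 1L) {
  if (!is.null(segment_lengths)) n_segments <- length(segment_lengths)
  stopifnot(n_segments >= 2L, length_range[1L] >= 10L,
            length_range[2L] >= length_range[1L], utr5 >= 3L, utr3 >= 0L)
  rng <- .seeded_rng(seed)
  seg_len <- if (!is.null(segment_lengths)) {
    stopifnot(all(segment_lengths >= 10L))
    as.integer(segment_lengths)
  } else {
    length_range[1L] +
      rng$rint(n_segments, length_range[2L] - length_range[1L] + 1L) - 1L
  }
  bounds <- cumsum(seg_len)
  region_end <- bounds[n_segments]
  n_aa <- region_end + nonstructural_len

  aa <- AA20[rng$rint(n_aa, 20L)]
  aa[1L] <- "M"
  # plant motif-conform windows at every boundary (incl. the region end)
  for (b in bounds) {
    aa[b] <- motif$p1_residues[1L]
    if (b + 1L <= n_aa) aa[b + 1L] <- motif$p1prime_residues[1L]
    for (f in motif$bonus_features) {
      at <- b + if (f$offset < 0L) f$offset + 1L else f$offset
      if (at >= 2L && at <= n_aa) aa[at] <- f$residues[1L]
    }
  }
  # remove unintended motif cores near the planted sites so each window is
  # locally unambiguous (resample the offending P1 residue)
  repeat {
    hits <- which(aa[-n_aa] %in% motif$p1_residues &
                    aa[-1L] %in% motif$p1prime_residues)
    spurious <- setdiff(hits[vapply(hits, function(h)
      any(abs(h - bounds) <= 4L), logical(1))], bounds)
    if (length(spurious) == 0L) break
    repl <- AA20[!AA20 %in% motif$p1_residues]
    aa[spurious] <- repl[rng$rint(length(spurious), length(repl))]
    for (b in bounds) {  # re-assert planted windows
      aa[b] <- motif$p1_residues[1L]
      if (b + 1L <= n_aa) aa[b + 1L] <- motif$p1prime_residues[1L]
    }
  }
  protein <- paste(aa, collapse = "")

  # back-translate with random synonymous codons
  codons <- vapply(aa, function(r) {
    opts <- CODON_TABLE[[r]]
    opts[rng$rint(1L, length(opts))]
  }, character(1))
  stop_codon <- STOP_CODONS[rng$rint(1L, 3L)]
  nt <- c("A", "C", "G", "T")
  for (attempt in 1:100) {
    u5 <- paste(nt[rng$rint(utr5, 4L)], collapse = "")
    # block in-frame upstream extension of the planted ORF
    u5 <- paste0(substr(u5, 1L, utr5 - 3L), "TAA")
    u3 <- if (utr3 > 0L) paste(nt[rng$rint(utr3, 4L)], collapse = "") else ""
    gseq <- paste0(u5, paste(codons, collapse = ""), stop_codon, u3,
                   strrep("A", polya_len))
    genome <- genome_record(paste0("synthetic_", seed), gseq,
                            "synthetic ground-truth genome")
    orf <- tryCatch(find_longest_orf(genome, min_aa = min(n_aa, 100L)),
                    error = function(e) NULL)
    if (!is.null(orf) && orf$start == utr5 + 1L &&
        orf$end == utr5 + 3L * (n_aa + 1L)) break
    if (attempt == 100L) stop("could not construct a genome whose longest ORF is the planted one")
  }

  segments <- data.frame(
    index = seq_len(n_segments),
    start = c(1L, utils::head(bounds, -1L) + 1L),
    end = bounds)
  structure(list(
    polyprotein = polyprotein_record(paste0("synthetic_", seed), protein,
                                     source_orf = orf),
    genome = genome,
    orf = orf,
    boundaries = bounds,
    segments = segments,
    region_end = region_end,
    params = list(n_segments = n_segments, length_range = length_range,
                  utr5 = utr5, utr3 = utr3,
                  nonstructural_len = nonstructural_len,
                  polya_len = polya_len, seed = seed,
                  motif_name = motif$name)),
    class = "synthetic_truth")
}

#' Simulate Edman N-terminal reads from a synthetic truth
#'
#' Reads are segment N-terminal prefixes with seeded per-cycle corruption:
#' substitution with probability `error_rate` and an undetermined ('X') call
#' with probability `x_rate` (capped so that no read exceeds the 40% X
#' limit). The default observes segments 2 and 4, emulating a study in which
#' the second and fourth structural proteins yielded N-terminal sequence.
#'
#' @param truth A [generate_truth()] result.
#' @param segments_observed Indices of segments with an Edman read.
#' @param read_len Read length (default 10, a decapeptide).
#' @param error_rate Per-cycle substitution probability.
#' @param x_rate Per-cycle undetermined probability.
#' @param seed Integer seed.
#' @return List of [edman_read()] objects (spot ids `E<segment index>`).
#' @export
simulate_edman <- function(truth, segments_observed = c(2L, 4L),
                           read_len = 10L, error_rate = 0, x_rate = 0,
                           seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            error_rate >= 0, error_rate < 1, x_rate >= 0, x_rate <= 1)
  rng <- .seeded_rng(seed)
  seq <- truth$polyprotein$sequence
  lapply(segments_observed, function(k) {
    st <- truth$segments$start[k]
    chars <- .seq_chars(substr(seq, st, min(st + read_len - 1L, nchar(seq))))
    max_x <- floor(0.4 * length(chars))
    n_x <- 0L
    for (i in seq_along(chars)) {
      u <- rng$runif(1L)
      if (u < error_rate) {
        alt <- AA20[AA20 != chars[i]]
        chars[i] <- alt[rng$rint(1L, length(alt))]
      } else if (u < error_rate + x_rate && n_x < max_x) {
        chars[i] <- "X"
        n_x <- n_x + 1L
      }
    }
    edman_read(paste0("E", k), paste(chars, collapse = ""))
  })
}

#' Simulate peptide-mass-fingerprint peak lists from a synthetic truth
#'
#' Each tryptic peptide (up to `max_missed` missed cleavages) of each
#' observed segment is detected independently with probability
#' `detection_prob`; detected neutral masses are perturbed by Gaussian
#' relative error with standard deviation `ppm_noise_sd` ppm, and uniform
#' contaminant peaks are added over the observed mass range. Masses carry
#' fixed cysteine carbamidomethylation, matching standard sample
#' preparation. The noise defaults define the package's standard stress
#' test: at 20 ppm noise a 75 ppm matching tolerance is a 3.75-sigma gate.
#'
#' @param truth A [generate_truth()] result.
#' @param segments_observed Indices of observed segments (default: all).
#' @param detection_prob Per-peptide detection probability (default 0.6).
#' @param ppm_noise_sd Mass-error standard deviation in ppm (default 20).
#' @param contaminant_fraction Contaminant peaks as a fraction of detected
#'   peaks (default 0.1).
#' @param max_missed Missed cleavages in the simulated digest (default 1).
#' @param min_peptide_mass,max_peptide_mass Instrument detection window in
#'   Da (default 500-5000, mirroring [pmf_config()]); peptides outside the
#'   window yield no peak. Segments with no detectable peptide (e.g. a small
#'   VP4-like peptide) produce no peak list, as in real virion preparations.
#' @param seed Integer seed.
#' @return Named list of [peak_list()] objects (spot ids `S<segment index>`).
#' @export
simulate_pmf <- function(truth, segments_observed = NULL,
                         detection_prob = 0.6, ppm_noise_sd = 20,
                         contaminant_fraction = 0.1, max_missed = 1L,
                         min_peptide_mass = 500, max_peptide_mass = 5000,
                         seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            detection_prob > 0, detection_prob <= 1,
            ppm_noise_sd >= 0, contaminant_fraction >= 0)
  if (is.null(segments_observed))
    segments_observed <- truth$segments$index
  rng <- .seeded_rng(seed)
  seq <- truth$polyprotein$sequence
  out <- lapply(segments_observed, function(k) {
    st <- truth$segments$start[k]
    en <- truth$segments$end[k]
    seg <- substr(seq, st, en)
    peps <- tryptic_digest(seg, max_missed = max_missed)
    chars <- .seq_chars(seg)
    masses <- .interval_masses(chars, peps$start, peps$end,
                               carbamidomethyl = TRUE)
    masses <- unique(masses)
    masses <- masses[masses >= min_peptide_mass & masses <= max_peptide_mass]
    if (length(masses) == 0L) return(NULL)
    detected <- masses[rng$runif(length(masses)) < detection_prob]
    if (length(detected) == 0L)
      detected <- masses[rng$rint(1L, length(masses))]
    if (ppm_noise_sd > 0)
      detected <- detected * (1 + rng$rnorm(length(detected)) * ppm_noise_sd * 1e-6)
    n_cont <- round(contaminant_fraction * length(detected))
    if (n_cont > 0L) {
      rg <- range(detected)
      if (diff(rg) == 0) rg <- c(800, 3000)
      detected <- c(detected, rg[1L] + rng$runif(n_cont) * diff(rg))
    }
    peak_list(paste0("S", k), detected)
  })
  names(out) <- paste0("S", segments_observed)
  out[!vapply(out, is.null, logical(1))]
}

#' Random unrooted binary tree
#'
#' Sequential random-attachment topology with branch lengths drawn uniformly
#' from `bl_range`. Used for simulation studies of the tree-inference code.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param bl_range Branch-length interval (default 0.05-0.5 substitutions
#'   per site).
#' @param seed Integer seed.
#' @return A `phylo` tree with tip labels `t01`, `t02`, ...
#' @export
random_topology <- function(n_taxa, bl_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(n_taxa >= 3L)
  rng <- .seeded_rng(seed)
  labels <- sprintf("t%02d", seq_len(n_taxa))
  # start from the 3-leaf star, attach remaining leaves to random edges
  edges <- matrix(c(n_taxa + 1L, 1L, n_taxa + 1L, 2L, n_taxa + 1L, 3L),
                  ncol = 2L, byrow = TRUE)
  next_internal <- n_taxa + 2L
  if (n_taxa > 3L) {
    for (leaf in 4:n_taxa) {
      e <- rng$rint(1L, nrow(edges))
      parent <- edges[e, 1L]; child <- edges[e, 2L]
      new_node <- next_internal
      next_internal <- next_internal + 1L
      edges[e, ] <- c(parent, new_node)
      edges <- rbind(edges, c(new_node, child), c(new_node, leaf))
    }
  }
  lens <- bl_range[1L] + rng$runif(nrow(edges)) * diff(bl_range)
  tree <- list(edge = edges, edge.length = lens, tip.label = labels,
               Nnode = next_internal - n_taxa - 1L)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Tree-implied additive distance matrix
#'
#' Patristic (path-length) distances between all leaf pairs of a tree; an
#' additive matrix by construction.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric labelled distance matrix.
#' @export
tree_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Simulate an alignment along a tree (Jukes-Cantor)
#'
#' Evolves a random root sequence down the tree: along a branch of length t,
#' each site changes to one of the three other bases with total probability
#' `3/4 (1 - exp(-4/3 rate t))`.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param n_sites Number of alignment columns.
#' @param rate Substitutions per site per unit branch length (default 1).
#' @param seed Integer seed.
#' @return An [alignment_block()] over the tree's tip labels.
#' @export
simulate_alignment <- function(tree, n_sites, rate = 1, seed = 1L) {
  stopifnot(n_sites >= 1L, rate >= 0)
  rng <- .seeded_rng(seed)
  nt <- c("A", "C", "G", "T")
  n_leaf <- length(tree$tip.label)
  n_node <- n_leaf + tree$Nnode
  seqs <- vector("list", n_node)
  root <- n_leaf + 1L
  seqs[[root]] <- rng$rint(n_sites, 4L)
  edge <- tree$edge
  # cladewise order guarantees parents are simulated before children
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1L]; child <- edge[e, 2L]
    t <- tree$edge.length[e]
    p_change <- 0.75 * (1 - exp(-4 / 3 * rate * t))
    s <- seqs[[parent]]
    mut <- rng$runif(n_sites) < p_change
    if (any(mut)) {
      shift <- rng$rint(sum(mut), 3L)          # 1..3: move to another base
      s[mut] <- ((s[mut] - 1L + shift) %% 4L) + 1L
    }
    seqs[[child]] <- s
  }
  alignment_block(tree$tip.label,
                  vapply(seq_len(n_leaf),
                         function(i) paste(nt[seqs[[i]]], collapse = ""),
                         character(1)))
}

#' Write a synthetic dataset to disk
#'
#' Writes the genome FASTA, Edman reads TSV, PMF peaks TSV and a truth JSON
#' for a generated scenario; the bundle is what the pipeline consumes.
#'
#' @param truth A [generate_truth()] result.
#' @param reads List of [edman_read()] objects.
#' @param peaks Named list of [peak_list()] objects.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_bundle <- function(truth, reads, peaks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_fa <- file.path(dir, "genome.fa")
  write_fasta(list(truth$genome), genome_fa)
  reads_tsv <- file.path(dir, "edman_reads.tsv")
  utils::write.table(
    data.frame(spot_id = vapply(reads, `[[`, character(1), "spot_id"),
               sequence = vapply(reads, `[[`, character(1), "residues")),
    reads_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  peaks_tsv <- file.path(dir, "peaks.tsv")
  ptab <- do.call(rbind, lapply(peaks, function(p)
    data.frame(spot_id = p$spot_id, mass_da = p$masses)))
  utils::write.table(ptab, peaks_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(boundaries = truth$boundaries, region_end = truth$region_end,
         segments = truth$segments, params = truth$params),
    truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(genome = genome_fa, reads = reads_tsv, peaks = peaks_tsv,
              truth = truth_json))
}
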