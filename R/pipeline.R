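# End-to-end orchestration: genome -> polyprotein -> evidence -> map ->
# report, with a machine-readable run manifest for provenance.

#' Run configuration
#'
#' Validates a configuration (given as a list or a YAML file path) for
#' [run_pipeline()]. Referenced input files must exist at validation time.
#'
#' @param config List or path to a YAML file. Recognized fields:
#'   `genome` (FASTA path, required), `edman` (reads TSV), `peaks` (peak TSV),
#'   `motif` (path to a key-value motif model; default model when absent),
#'   `region_end` (`"AUTO"` or integer), `min_aa` (ORF search threshold,
#'   default 100), `tolerance_ppm` (default 75), `max_missed` (default 1),
#'   `max_mismatches` (Edman, default 1), `mh_plus` (peaks are MH+ m/z),
#'   `auto_window` (fraction interval for AUTO region end, default
#'   `c(0.30, 0.45)`), `out_dir` (required), `seed` (default 1).
#' @return Object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(edman = NULL, peaks = NULL, motif = NULL,
                   region_end = "AUTO", min_aa = 100L, tolerance_ppm = 75,
                   max_missed = 1L, max_mismatches = 1L, mh_plus = FALSE,
                   auto_window = c(0.30, 0.45), seed = 1L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$genome)) stop("config validation: 'genome' is required")
  if (is.null(config$out_dir)) stop("config validation: 'out_dir' is required")
  for (k in c("genome", "edman", "peaks", "motif")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop("config validation: ", k, " file not found: ", config[[k]])
  }
  structure(config, class = "run_config")
}

#' Run the full cleavage-mapping pipeline
#'
#' Stages: sequence reading and ORF translation; Edman read localization;
#' per-spot PMF matching against the polyprotein; motif scanning; map
#' assembly; report writing. Intermediate artifacts and a run manifest
#' (parameters, seed, file checksums) are persisted to the output directory,
#' so identical configurations reproduce byte-identical bundles.
#'
#' @param config A [run_config()] (or list / YAML path accepted by it).
#' @return The assembled `cleavage_map`, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "seqio"
  result <- tryCatch({
    message("[seqio] reading genome: ", cfg$genome)
    recs <- read_sequences(cfg$genome)
    if (length(recs) == 0L) stop("no records in ", cfg$genome)
    genome <- recs[[1L]]
    orf <- find_longest_orf(genome, min_aa = cfg$min_aa)
    poly <- translate_orf(genome, orf)
    gstats <- genome_stats(genome, orf, exclude_polya_tail = TRUE)
    message("[seqio] polyprotein of ", poly$length, " aa (ORF ",
            orf$start, "..", orf$end, ")")

    stage <- "edman"
    anchors <- NULL
    if (!is.null(cfg$edman)) {
      reads <- read_edman_tsv(cfg$edman)
      anchors <- locate_reads(reads, poly, cfg$max_mismatches)
      message("[edman] ", nrow(anchors), " anchor(s) from ",
              length(reads), " read(s)")
    }

    stage <- "pmf"
    pmf_results <- list()
    if (!is.null(cfg$peaks)) {
      plists <- read_peak_lists(cfg$peaks, mh_plus = isTRUE(cfg$mh_plus))
      pconf <- pmf_config(tolerance_ppm = cfg$tolerance_ppm,
                          max_missed = cfg$max_missed,
                          allow_semitryptic_cterm = TRUE)
      pmf_results <- lapply(plists, function(pl)
        match_peaks(pl, list(poly), pconf)[[1L]])
      message("[pmf] matched ", length(pmf_results), " spot(s)")
    }

    stage <- "motif"
    model <- if (is.null(cfg$motif)) cleavage_motif_model()
             else read_motif_model(cfg$motif)
    sites <- scan_cleavage_sites(poly, model)
    md <- scan_divergent_md(poly)
    cand <- rbind(sites, md)
    cand <- cand[order(cand$cleavage_after), , drop = FALSE]
    message("[motif] ", nrow(cand), " candidate site(s)")

    stage <- "mapper"
    region_end <- cfg$region_end
    if (identical(region_end, "AUTO")) {
      region_end <- .auto_region_end(poly, cand, anchors, cfg$auto_window)
      message("[mapper] AUTO region end: ", region_end)
    }
    ev <- evidence_set(anchors = anchors, pmf_results = pmf_results,
                       candidate_sites = cand,
                       spot_observations = cfg$spot_observations,
                       region_end = as.integer(region_end))
    map <- assemble_map(poly, ev)

    stage <- "report"
    paths <- write_report(map, out, genome = genome, orf = orf)
    write_fasta(list(poly), file.path(out, "polyprotein.fa"))
    utils::write.table(cand, file.path(out, "candidate_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("polymap")),
      seed = cfg$seed,
      parameters = cfg[setdiff(names(cfg), "spot_observations")],
      genome_stats = list(length = gstats$length, utr5 = gstats$utr5_len,
                          utr3 = gstats$utr3_len,
                          base_fractions = as.list(gstats$base_fractions)),
      outputs = as.list(vapply(unname(paths), function(f)
        unname(tools::md5sum(f)), character(1))))
    names(manifest$outputs) <- basename(unname(paths))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    map
  }, error = function(e) {
    jsonlite::write_json(list(failed_stage = stage,
                              error = conditionMessage(e)),
                         file.path(out, "manifest.json"), auto_unbox = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# AUTO region-end policy: the highest-scoring candidate site past all other
# evidence, searched within a window expressed as fractions of the
# polyprotein length (structural regions of picorna-like polyproteins
# occupy roughly the N-terminal third). Ties break 5'-most.
.auto_region_end <- function(poly, cand, anchors, window = c(0.30, 0.45)) {
  lo <- max(1L, floor(window[1L] * poly$length))
  hi <- ceiling(window[2L] * poly$length)
  floor_pos <- 0L
  if (!is.null(anchors) && nrow(anchors) > 0L)
    floor_pos <- max(anchors$implied_cleavage_after)
  inside <- cand[cand$cleavage_after >= max(lo, floor_pos + 1L) &
                   cand$cleavage_after <= hi, , drop = FALSE]
  if (nrow(inside) == 0L)
    stop("AUTO region end: no candidate site in window [", lo, ", ", hi, "]")
  best <- which(inside$score == max(inside$score))
  inside$cleavage_after[best[which.min(inside$cleavage_after[best])]]
}
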