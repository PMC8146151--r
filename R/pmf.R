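# Peptide mass fingerprinting: ppm-tolerance matching of observed neutral
# masses against in silico digests, interval coverage, and decoy-based FDR.

#' PMF search configuration
#'
#' @param tolerance_ppm Relative mass tolerance in ppm (default 75).
#' @param fixed_mods Fixed modifications applied to every target residue
#'   (default carbamidomethylation of C).
#' @param variable_mods Variable modifications (default oxidation of M).
#' @param max_variable_mods Maximum variable modification events per peptide
#'   (default 2; combinatorial control).
#' @param max_missed Maximum missed cleavages in the digest (default 1).
#' @param allow_semitryptic_cterm Also consider peptides ending at the
#'   protein C-terminus whose C-terminal cut is non-tryptic (default `FALSE`).
#' @param fdr_threshold Decoy-FDR acceptance threshold (default 0.05).
#' @param min_peptide_mass,max_peptide_mass Detection window in Da (default
#'   500-5000, a typical MALDI reflectron acquisition range); theoretical
#'   peptides outside the window are not considered, which also removes the
#'   mass-degenerate 1-4 residue peptides that would otherwise match
#'   everywhere.
#' @return Object of class `pmf_config`.
#' @export
pmf_config <- function(tolerance_ppm = 75, fixed_mods = "carbamidomethyl",
                       variable_mods = "oxidation", max_variable_mods = 2L,
                       max_missed = 1L, allow_semitryptic_cterm = FALSE,
                       fdr_threshold = 0.05, min_peptide_mass = 500,
                       max_peptide_mass = 5000) {
  stopifnot(tolerance_ppm > 0, fdr_threshold > 0, fdr_threshold < 1,
            max_variable_mods >= 0L, max_missed >= 0L,
            min_peptide_mass >= 0, max_peptide_mass > min_peptide_mass)
  structure(list(tolerance_ppm = tolerance_ppm, fixed_mods = fixed_mods,
                 variable_mods = variable_mods,
                 max_variable_mods = as.integer(max_variable_mods),
                 max_missed = as.integer(max_missed),
                 allow_semitryptic_cterm = allow_semitryptic_cterm,
                 fdr_threshold = fdr_threshold,
                 min_peptide_mass = min_peptide_mass,
                 max_peptide_mass = max_peptide_mass),
            class = "pmf_config")
}

#' Peak list of neutral monoisotopic masses
#'
#' @param spot_id Identifier of the gel spot / spectrum.
#' @param masses Numeric vector of neutral monoisotopic masses in Da;
#'   sorted ascending on construction, duplicates allowed.
#' @return Object of class `peak_list`.
#' @export
peak_list <- function(spot_id, masses) {
  masses <- as.numeric(masses)
  stopifnot(length(masses) > 0L, all(masses > 0), !anyNA(masses))
  structure(list(spot_id = as.character(spot_id), masses = sort(masses)),
            class = "peak_list")
}

#' Read peak lists from a two-column TSV (spot_id, mass_da)
#'
#' @param path TSV path with columns `spot_id` and `mass_da`.
#' @param mh_plus If `TRUE` the file holds singly protonated m/z values;
#'   one proton mass is subtracted to obtain neutral masses.
#' @return Named list of [peak_list()] objects, one per spot.
#' @export
read_peak_lists <- function(path, mh_plus = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("spot_id", "mass_da") %in% names(tab)))
    stop("peak-list file must have columns spot_id and mass_da: ", path)
  masses <- tab$mass_da
  if (mh_plus) masses <- masses - PROTON_MASS
  split_masses <- split(masses, tab$spot_id)
  out <- lapply(names(split_masses),
                function(s) peak_list(s, split_masses[[s]]))
  stats::setNames(out, names(split_masses))
}

# Digest a candidate and expand variable-modification states.
# Returns a data.frame with theoretical neutral monoisotopic masses.
.theoretical_peptides <- function(candidate, cfg) {
  seq <- .protein_seq(candidate)
  peps <- tryptic_digest(candidate, max_missed = cfg$max_missed)
  if (cfg$allow_semitryptic_cterm) {
    semi <- semitryptic_cterm_peptides(candidate, max_missed = cfg$max_missed)
    semi <- semi[!(paste(semi$start, semi$end) %in%
                     paste(peps$start, peps$end)), , drop = FALSE]
    semi$semitryptic <- rep(TRUE, nrow(semi))
    peps$semitryptic <- rep(FALSE, nrow(peps))
    peps <- rbind(peps, semi)
  } else {
    peps$semitryptic <- rep(FALSE, nrow(peps))
  }
  chars <- .seq_chars(seq)
  cam <- "carbamidomethyl" %in% cfg$fixed_mods
  base <- .interval_masses(chars, peps$start, peps$end,
                           carbamidomethyl = cam)
  n_m <- .interval_residue_counts(chars, peps$start, peps$end, "M")
  ox_delta <- .mod_delta("oxidation", "monoisotopic")$delta
  use_ox <- "oxidation" %in% cfg$variable_mods
  max_ox <- if (use_ox) pmin(n_m, cfg$max_variable_mods) else rep(0L, nrow(peps))
  reps <- max_ox + 1L
  idx <- rep(seq_len(nrow(peps)), reps)
  ox <- unlist(lapply(reps, function(r) 0:(r - 1L)), use.names = FALSE)
  out <- peps[idx, , drop = FALSE]
  out$n_ox <- ox
  out$theo_mass <- base[idx] + ox * ox_delta
  out <- out[out$theo_mass >= cfg$min_peptide_mass &
               out$theo_mass <= cfg$max_peptide_mass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match observed peaks against candidate proteins
#'
#' A peak matches a (peptide, modification-state) pair when the relative mass
#' error `|obs - theo| / theo * 1e6` is at most the configured ppm tolerance.
#' All matches are reported; a peak may match several peptides. Coverage
#' blocks are the merged intervals of all matched peptides of a candidate.
#'
#' @param peaks A [peak_list()].
#' @param candidates Named list of candidate proteins
#'   ([polyprotein_record()]s or amino-acid strings).
#' @param cfg A [pmf_config()].
#' @return Named list of `pmf_result` objects, one per candidate, each with
#'   `matches` (data frame), `coverage_blocks`, `matched_peak_count`,
#'   `coverage_fraction`.
#' @export
match_peaks <- function(peaks, candidates, cfg = pmf_config()) {
  stopifnot(inherits(peaks, "peak_list"), inherits(cfg, "pmf_config"))
  if (!is.list(candidates)) candidates <- list(candidates)
  if (length(candidates) == 0L) stop("no candidate proteins supplied")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    names(candidates) <- vapply(candidates, .protein_id, character(1))
  }
  out <- lapply(names(candidates), function(id) {
    .match_one(peaks, candidates[[id]], id, cfg)
  })
  stats::setNames(out, names(candidates))
}

.match_one <- function(peaks, candidate, candidate_id, cfg) {
  theo <- .theoretical_peptides(candidate, cfg)
  obs <- peaks$masses
  tol <- cfg$tolerance_ppm
  # window per peak via sorted theoretical masses
  ord <- order(theo$theo_mass)
  tm <- theo$theo_mass[ord]
  lo <- findInterval(obs * (1 - tol * 1e-6), tm) + 1L
  hi <- findInterval(obs * (1 + tol * 1e-6), tm)
  n_hits <- pmax(hi - lo + 1L, 0L)
  peak_idx <- rep(seq_along(obs), n_hits)
  theo_idx <- unlist(mapply(function(a, b) if (a <= b) a:b else integer(),
                            lo, hi, SIMPLIFY = FALSE), use.names = FALSE)
  if (length(theo_idx) > 0L) {
    rows <- theo[ord[theo_idx], , drop = FALSE]
    err <- (obs[peak_idx] - rows$theo_mass) / rows$theo_mass * 1e6
    keep <- abs(err) <= tol   # guard the open edges of the prefilter window
    matches <- data.frame(
      spot_id = peaks$spot_id,
      peak_idx = peak_idx[keep],
      peak_mass = obs[peak_idx][keep],
      start = rows$start[keep], end = rows$end[keep],
      seq = rows$seq[keep],
      missed_cleavages = rows$missed_cleavages[keep],
      semitryptic = rows$semitryptic[keep],
      n_ox = rows$n_ox[keep],
      theo_mass = rows$theo_mass[keep],
      error_ppm = err[keep],
      stringsAsFactors = FALSE)
  } else {
    matches <- data.frame(spot_id = character(), peak_idx = integer(),
                          peak_mass = numeric(),
                          start = integer(), end = integer(),
                          seq = character(), missed_cleavages = integer(),
                          semitryptic = logical(), n_ox = integer(),
                          theo_mass = numeric(), error_ppm = numeric(),
                          stringsAsFactors = FALSE)
  }
  blocks <- merge_coverage(matches)
  len <- nchar(.protein_seq(candidate))
  covered <- if (nrow(blocks)) sum(blocks$end - blocks$start + 1L) else 0L
  structure(list(spot_id = peaks$spot_id,
                 candidate_id = candidate_id,
                 matches = matches,
                 coverage_blocks = blocks,
                 matched_peak_count = length(unique(matches$peak_idx)),
                 coverage_fraction = covered / len,
                 n_peaks = length(obs)),
            class = "pmf_result")
}

#' Merge matched-peptide intervals into coverage blocks
#'
#' Overlapping or bookended (end + 1 == next start) intervals are merged;
#' the result is sorted and disjoint.
#'
#' @param matches Data frame with `start` and `end` columns (as produced by
#'   [match_peaks()]), or any interval table referencing one parent.
#' @return Data frame with columns `start`, `end`.
#' @export
merge_coverage <- function(matches) {
  if (!is.null(matches$spot_id) && length(unique(matches$spot_id)) > 1L)
    stop("cannot merge coverage across different spots: ",
         paste(unique(matches$spot_id), collapse = ", "))
  if (is.null(matches$start) || nrow(matches) == 0L)
    return(data.frame(start = integer(), end = integer()))
  iv <- unique(data.frame(start = as.integer(matches$start),
                          end = as.integer(matches$end)))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  starts <- iv$start[1L]
  ends <- iv$end[1L]
  for (k in seq_len(nrow(iv))[-1L]) {
    j <- length(starts)
    if (iv$start[k] <= ends[j] + 1L) {
      ends[j] <- max(ends[j], iv$end[k])
    } else {
      starts <- c(starts, iv$start[k])
      ends <- c(ends, iv$end[k])
    }
  }
  data.frame(start = starts, end = ends)
}

#' Decoy-based false-discovery estimate for a PMF identification
#'
#' Builds decoy sequences from the candidate (its reversal, then seeded
#' residue shuffles), matches the same peak list against each decoy, and
#' estimates FDR as the mean decoy matched-peak count divided by the target
#' matched-peak count. The identification is accepted when the estimate does
#' not exceed the configured threshold.
#'
#' @param peaks A [peak_list()].
#' @param candidate Target protein (record or string).
#' @param cfg A [pmf_config()].
#' @param n_decoys Number of decoy sequences (default 20; the first is the
#'   reversal, the rest are shuffles).
#' @param seed Integer seed for the shuffles.
#' @return List with `fdr`, `accepted`, `target_count`, `decoy_mean_count`,
#'   and `status` (`"ok"` or `"no_target_matches"`).
#' @export
decoy_fdr <- function(peaks, candidate, cfg = pmf_config(), n_decoys = 20L,
                      seed = 1L) {
  stopifnot(n_decoys >= 1L)
  seq <- .protein_seq(candidate)
  target <- .match_one(peaks, seq, "target", cfg)
  if (target$matched_peak_count == 0L) {
    warning("no target matches; FDR reported as 1.0")
    return(list(fdr = 1.0, accepted = FALSE, target_count = 0L,
                decoy_mean_count = NA_real_, status = "no_target_matches"))
  }
  chars <- .seq_chars(seq)
  decoys <- character(n_decoys)
  decoys[1L] <- paste(rev(chars), collapse = "")
  if (n_decoys > 1L) {
    rng <- .seeded_rng(seed)
    for (k in 2:n_decoys) {
      decoys[k] <- paste(chars[rng$sample(length(chars))], collapse = "")
    }
  }
  counts <- vapply(decoys, function(d) {
    .match_one(peaks, d, "decoy", cfg)$matched_peak_count
  }, numeric(1))
  fdr <- mean(counts) / target$matched_peak_count
  list(fdr = fdr, accepted = fdr <= cfg$fdr_threshold,
       target_count = target$matched_peak_count,
       decoy_mean_count = mean(counts), status = "ok")
}

# Local RNG that does not disturb the global .Random.seed.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  run <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    res <- expr()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    res
  }
  list(
    sample = function(n, size = n, replace = FALSE)
      run(function() sample.int(n, size, replace = replace)),
    runif = function(n, min = 0, max = 1)
      run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      run(function() stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob)
      run(function() stats::rbinom(n, size, prob)),
    rint = function(n, max)
      run(function() sample.int(max, n, replace = TRUE))
  )
}

#' @export
print.pmf_result <- function(x, ...) {
  cat("<pmf_result> spot", x$spot_id, "vs", x$candidate_id, "-",
      x$matched_peak_count, "of", x$n_peaks, "peaks matched,",
      nrow(x$coverage_blocks), "coverage blocks,",
      sprintf("%.1f%% coverage\n", 100 * x$coverage_fraction))
  invisible(x)
}
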