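# Independent brute-force oracles and tiny generators used across the suite.
# These deliberately re-derive results by the most naive route available so
# that they share no code path with the implementation they check.

AAs <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len, alphabet = AAs) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# naive tryptic digestion by character scan (no shared code with the package)
oracle_tryptic_fragments <- function(seq, not_before_p = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  cuts <- integer()
  for (i in seq_len(max(n - 1L, 0L))) {
    if (ch[i] %in% c("K", "R") && !(not_before_p && ch[i + 1L] == "P"))
      cuts <- c(cuts, i)
  }
  b <- c(0L, cuts, n)
  data.frame(start = head(b, -1L) + 1L, end = b[-1L])
}

# peptide monoisotopic mass straight from the shipped table (simple sum)
oracle_mono_mass <- function(seq, cam = TRUE, n_ox = 0L) {
  tab <- residue_masses()
  m <- setNames(tab$monoisotopic, tab$residue)
  ch <- strsplit(seq, "")[[1]]
  out <- sum(m[ch]) + 18.010565
  if (cam) out <- out + 57.021464 * sum(ch == "C")
  out + 15.994915 * n_ox
}

# exhaustive PMF matching: every (peptide, oxidation-state) pair vs every peak
oracle_pmf_matches <- function(masses, protein, cfg) {
  frags <- oracle_tryptic_fragments(protein)
  nfrag <- nrow(frags)
  peps <- list()
  for (m in 0:cfg$max_missed) {
    for (i in seq_len(max(nfrag - m, 0L))) {
      peps[[length(peps) + 1L]] <- c(frags$start[i], frags$end[i + m])
    }
  }
  if (cfg$allow_semitryptic_cterm) {
    n <- nchar(protein)
    for (i in seq_len(nfrag)) {
      st <- frags$start[i]
      n_internal <- sum(frags$end >= st & frags$end < n)
      if (n_internal <= cfg$max_missed)
        peps[[length(peps) + 1L]] <- c(st, n)
    }
  }
  peps <- unique(peps)
  hits <- list()
  for (p in peps) {
    pep_seq <- substr(protein, p[1], p[2])
    n_m <- sum(strsplit(pep_seq, "")[[1]] == "M")
    for (ox in 0:min(n_m, cfg$max_variable_mods)) {
      theo <- oracle_mono_mass(pep_seq, cam = TRUE, n_ox = ox)
      if (theo < cfg$min_peptide_mass || theo > cfg$max_peptide_mass) next
      for (k in seq_along(masses)) {
        if (abs(masses[k] - theo) / theo * 1e6 <= cfg$tolerance_ppm) {
          hits[[length(hits) + 1L]] <-
            data.frame(peak_idx = k, start = p[1], end = p[2], n_ox = ox,
                       theo_mass = theo)
        }
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(peak_idx = integer(), start = integer(),
                      end = integer(), n_ox = integer(),
                      theo_mass = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$peak_idx, out$start, out$end, out$n_ox), ]
}

# dense grid search for the isoelectric point
oracle_pi_grid <- function(seq, step = 1e-5) {
  ph <- seq(0, 14, by = step)
  ch <- net_charge(seq, ph)
  ph[which.min(abs(ch))]
}

# naive sliding-window read localization
oracle_locate <- function(read, protein, max_mm) {
  r <- strsplit(read, "")[[1]]
  p <- strsplit(protein, "")[[1]]
  L <- length(r)
  hits <- integer(); mism <- integer()
  for (s in seq_len(length(p) - L + 1L)) {
    mm <- sum(r != "X" & r != p[s:(s + L - 1L)])
    if (mm <= max_mm) { hits <- c(hits, s); mism <- c(mism, mm) }
  }
  data.frame(start = hits, mismatches = mism)
}

# naive per-position motif scoring
oracle_motif_scan <- function(protein, model) {
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  out <- data.frame(cleavage_after = integer(), score = integer())
  for (i in seq_len(n - 1L)) {
    if (!(ch[i] %in% model$p1_residues && ch[i + 1L] %in% model$p1prime_residues))
      next
    sc <- model$core_weight
    for (b in model$bonus_features) {
      at <- if (b$offset < 0) i + b$offset + 1L else i + b$offset
      if (at >= 1L && at <= n && ch[at] %in% b$residues) sc <- sc + b$weight
    }
    if (sc >= model$min_score)
      out <- rbind(out, data.frame(cleavage_after = i, score = sc))
  }
  out
}

# naive p-distance for one pair
oracle_pdist_pair <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  ok <- a != "-" & b != "-"
  sum(a[ok] != b[ok]) / sum(ok)
}

# canonical split set of a phylo tree, via ape's bipartition machinery
oracle_splits <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  all_lab <- sort(labs)
  out <- character()
  for (p in parts) {
    side <- sort(labs[p])
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    canon <- if (all_lab[1L] %in% side) sort(setdiff(all_lab, side)) else side
    out <- c(out, paste(canon, collapse = "|"))
  }
  sort(unique(out))
}

same_topology <- function(t1, t2) {
  setequal(oracle_splits(ape::unroot(t1)), oracle_splits(ape::unroot(t2)))
}

# standard paper-layout evidence bundle for mapper tests
make_scenario <- function(seed, noiseless = TRUE, edman_segs = c(2L, 4L),
                          n_segments = 5L) {
  truth <- generate_truth(n_segments = n_segments, seed = seed)
  poly <- truth$polyprotein
  reads <- simulate_edman(truth, segments_observed = edman_segs, seed = seed)
  anch <- locate_reads(reads, poly)
  peaks <- if (noiseless) {
    simulate_pmf(truth, detection_prob = 1, ppm_noise_sd = 0,
                 contaminant_fraction = 0, seed = seed)
  } else {
    simulate_pmf(truth, seed = seed)
  }
  cfg <- pmf_config()
  pres <- lapply(peaks, function(p) match_peaks(p, list(poly), cfg)[[1]])
  sites <- rbind(scan_cleavage_sites(poly), scan_divergent_md(poly))
  segmw <- vapply(seq_len(n_segments), function(k)
    protein_average_mw(substr(poly$sequence, truth$segments$start[k],
                              truth$segments$end[k])), numeric(1))
  spot_obs <- data.frame(spot_id = paste0("E", edman_segs),
                         apparent_mw_kda = segmw[edman_segs])
  ev <- evidence_set(anchors = anch, pmf_results = pres,
                     candidate_sites = sites, spot_observations = spot_obs,
                     region_end = truth$region_end)
  list(truth = truth, poly = poly, evidence = ev, segmw = segmw)
}

recovers_truth <- function(seed, noiseless = TRUE, edman_segs = c(2L, 4L)) {
  sc <- make_scenario(seed, noiseless, edman_segs)
  map <- tryCatch(assemble_map(sc$poly, sc$evidence),
                  error = function(e) NULL)
  if (is.null(map)) return(FALSE)
  identical(as.integer(map$boundaries),
            as.integer(head(sc$truth$boundaries, -1L)))
}
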