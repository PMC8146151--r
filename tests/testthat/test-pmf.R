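test_that("a peak at the exact theoretical mass matches with zero error", {
  prot <- "MAGICPEPTIDEKWITHSEVERALRESIDUESK"
  prot <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "A", prot)
  peps <- tryptic_digest(prot, max_missed = 0L)
  target <- peps$seq[which.max(nchar(peps$seq))]
  m <- peptide_mass(target)
  res <- match_peaks(peak_list("s1", m), list(p = prot), pmf_config())$p
  expect_gte(nrow(res$matches), 1L)
  hit <- res$matches[res$matches$seq == target, ]
  expect_equal(hit$error_ppm, 0, tolerance = 1e-9)
})

test_that("the ppm tolerance is a sharp boundary", {
  prot <- "SAMPLEPRTEINWITHKLYSINEANDARGININEK"
  prot <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "G", prot)
  target <- tryptic_digest(prot, max_missed = 0L)$seq[1]
  m <- peptide_mass(target)
  cfg <- pmf_config(tolerance_ppm = 75)
  at <- function(ppm) {
    r <- match_peaks(peak_list("s", m * (1 + ppm * 1e-6)), list(p = prot), cfg)$p
    sum(r$matches$seq == target)
  }
  expect_equal(at(74), 1L)
  expect_equal(at(76), 0L)
})

test_that("matching equals exhaustive enumeration on random instances", {
  set.seed(17)
  for (i in 1:25) {
    prot <- random_peptide(sample(50:300, 1))
    cfg <- pmf_config(tolerance_ppm = sample(c(20, 75, 200), 1),
                      max_missed = sample(0:2, 1),
                      allow_semitryptic_cterm = sample(c(TRUE, FALSE), 1))
    # peak list: some true peptide masses (possibly perturbed), some random
    frags <- oracle_tryptic_fragments(prot)
    true_m <- vapply(seq_len(nrow(frags)), function(k)
      oracle_mono_mass(substr(prot, frags$start[k], frags$end[k])), numeric(1))
    masses <- c(sample(true_m, min(10, length(true_m))) *
                  (1 + rnorm(min(10, length(true_m)), 0, 3e-5)),
                runif(10, 500, 3000))
    masses <- masses[masses > 0]
    res <- match_peaks(peak_list("s", masses), list(p = prot), cfg)$p
    want <- oracle_pmf_matches(sort(masses), prot, cfg)
    got <- res$matches[order(res$matches$peak_idx, res$matches$start,
                             res$matches$end, res$matches$n_ox),
                       c("peak_idx", "start", "end", "n_ox")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want[, c("peak_idx", "start", "end", "n_ox")])
  }
})

test_that("coverage merging joins overlapping and bookended intervals", {
  iv <- data.frame(start = c(1L, 5L, 30L), end = c(10L, 20L, 40L))
  expect_equal(merge_coverage(iv),
               data.frame(start = c(1L, 30L), end = c(20L, 40L)))
  expect_equal(nrow(merge_coverage(data.frame(start = integer(),
                                              end = integer()))), 0L)
  # bookended: [1,10] and [11,20] merge
  expect_equal(merge_coverage(data.frame(start = c(1L, 11L),
                                         end = c(10L, 20L))),
               data.frame(start = 1L, end = 20L))
  expect_error(merge_coverage(data.frame(spot_id = c("a", "b"),
                                         start = 1:2, end = 3:4)),
               "different spots")
})

test_that("complete peak lists give full single-block coverage", {
  set.seed(23)
  prot <- random_peptide(150)
  peps <- tryptic_digest(prot, max_missed = 0L)
  masses <- vapply(peps$seq, peptide_mass, numeric(1))
  cfg <- pmf_config(min_peptide_mass = 0, max_peptide_mass = 1e6)
  res <- match_peaks(peak_list("s", masses), list(p = prot), cfg)$p
  expect_equal(res$coverage_fraction, 1)
  expect_equal(res$coverage_blocks, data.frame(start = 1L, end = 150L))
})

test_that("matches grow monotonically in tolerance and missed cleavages", {
  set.seed(31)
  prot <- random_peptide(200)
  masses <- runif(30, 500, 3000)
  key <- function(res) paste(res$matches$peak_idx, res$matches$start,
                             res$matches$end, res$matches$n_ox)
  pl <- peak_list("s", masses)
  for (i in 1:5) {
    t1 <- runif(1, 10, 150); t2 <- t1 + runif(1, 10, 300)
    r1 <- match_peaks(pl, list(p = prot), pmf_config(tolerance_ppm = t1))$p
    r2 <- match_peaks(pl, list(p = prot), pmf_config(tolerance_ppm = t2))$p
    expect_true(all(key(r1) %in% key(r2)))
    r3 <- match_peaks(pl, list(p = prot),
                      pmf_config(tolerance_ppm = t1, max_missed = 2L))$p
    expect_true(all(key(r1) %in% key(r3)))
  }
})

test_that("decoy FDR accepts true identifications and flags degenerate ones", {
  set.seed(41)
  prot <- random_peptide(250)
  peps <- tryptic_digest(prot, max_missed = 1L)
  masses <- vapply(peps$seq[nchar(peps$seq) >= 6], peptide_mass, numeric(1))
  masses <- masses[masses >= 500 & masses <= 5000]
  res <- decoy_fdr(peak_list("s", masses), prot,
                   pmf_config(tolerance_ppm = 10), n_decoys = 10L, seed = 2L)
  expect_true(res$accepted)
  expect_lt(res$fdr, 0.05)

  # single-residue homopolymer: decoys are the target itself
  aaaa <- "AAAAAAAAAA"
  m_all <- peptide_mass(aaaa)
  r2 <- decoy_fdr(peak_list("s", m_all), aaaa,
                  pmf_config(min_peptide_mass = 0), n_decoys = 5L, seed = 1L)
  expect_equal(r2$fdr, 1.0)
  expect_false(r2$accepted)

  expect_warning(
    r3 <- decoy_fdr(peak_list("s", 999.777), prot, pmf_config(tolerance_ppm = 1),
                    n_decoys = 3L, seed = 1L),
    "no target matches")
  expect_equal(r3$fdr, 1.0)
  expect_equal(r3$status, "no_target_matches")
})

test_that("random peak lists are rarely accepted at the 5% threshold", {
  set.seed(53)
  prot <- random_peptide(300)
  cfg <- pmf_config()
  accepted <- vapply(1:60, function(i) {
    pl <- peak_list(paste0("r", i), runif(20, 800, 3000))
    suppressWarnings(decoy_fdr(pl, prot, cfg, n_decoys = 10L, seed = i)$accepted)
  }, logical(1))
  expect_lte(mean(accepted), 0.10)
})

test_that("MH+ peak lists are converted to neutral masses on load", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spot_id\tmass_da", "s1\t1001.007276", "s1\t1501.007276"), tsv)
  pl <- read_peak_lists(tsv, mh_plus = TRUE)
  expect_equal(pl$s1$masses, c(1000, 1500), tolerance = 1e-9)
})
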