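test_that("generators are pure functions of their seed", {
  t1 <- generate_truth(seed = 12)
  t2 <- generate_truth(seed = 12)
  expect_identical(t1$polyprotein$sequence, t2$polyprotein$sequence)
  expect_identical(t1$genome$sequence, t2$genome$sequence)
  expect_identical(t1$boundaries, t2$boundaries)
  t3 <- generate_truth(seed = 13)
  expect_false(identical(t1$polyprotein$sequence, t3$polyprotein$sequence))

  p1 <- simulate_pmf(t1, seed = 4)
  p2 <- simulate_pmf(t1, seed = 4)
  expect_identical(lapply(p1, `[[`, "masses"), lapply(p2, `[[`, "masses"))
  e1 <- simulate_edman(t1, error_rate = 0.1, x_rate = 0.1, seed = 4)
  e2 <- simulate_edman(t1, error_rate = 0.1, x_rate = 0.1, seed = 4)
  expect_identical(vapply(e1, `[[`, character(1), "residues"),
                   vapply(e2, `[[`, character(1), "residues"))
})

test_that("the generated genome encodes the generated polyprotein", {
  for (seed in c(1, 44)) {
    truth <- generate_truth(seed = seed)
    orf <- find_longest_orf(truth$genome, min_aa = 100L)
    expect_equal(orf$start, truth$params$utr5 + 1L)
    expect_identical(translate_orf(truth$genome, orf)$sequence,
                     truth$polyprotein$sequence)
  }
})

test_that("motif scanning finds every planted boundary", {
  for (seed in c(6, 18)) {
    truth <- generate_truth(seed = seed)
    sites <- scan_cleavage_sites(truth$polyprotein)
    expect_true(all(truth$boundaries %in% sites$cleavage_after))
  }
})

test_that("noise-free reads are exact prefixes and anchor correctly", {
  truth <- generate_truth(seed = 33)
  reads <- simulate_edman(truth, segments_observed = 1:5, seed = 1)
  starts <- truth$segments$start
  for (k in seq_along(reads)) {
    expect_identical(reads[[k]]$residues,
                     substr(truth$polyprotein$sequence, starts[k],
                            starts[k] + 9L))
  }
  anch <- locate_reads(reads, truth$polyprotein, 0L)
  expect_setequal(anch$start[!anch$ambiguous],
                  starts[starts %in% anch$start])
})

test_that("undetermined-cycle corruption respects the 40% X cap", {
  truth <- generate_truth(seed = 3)
  reads <- simulate_edman(truth, x_rate = 1, seed = 1)
  for (r in reads) {
    n_x <- sum(strsplit(r$residues, "")[[1]] == "X")
    expect_lte(n_x, 4L)
  }
})

test_that("perfect detection yields full segment coverage", {
  truth <- generate_truth(seed = 10)
  peaks <- simulate_pmf(truth, detection_prob = 1, ppm_noise_sd = 0,
                        contaminant_fraction = 0, max_missed = 0L,
                        min_peptide_mass = 0, max_peptide_mass = 1e9,
                        seed = 1)
  cfg <- pmf_config(min_peptide_mass = 0, max_peptide_mass = 1e9,
                    max_missed = 0L)
  for (k in truth$segments$index) {
    seg <- substr(truth$polyprotein$sequence, truth$segments$start[k],
                  truth$segments$end[k])
    res <- match_peaks(peaks[[paste0("S", k)]], list(seg = seg), cfg)$seg
    expect_equal(res$coverage_fraction, 1.0)
  }
})

test_that("20 ppm mass noise stays inside the 75 ppm gate", {
  # 75 ppm at 20 ppm noise is a 3.75-sigma gate: P(match) ~ 0.99982
  truth <- generate_truth(seed = 77)
  peps <- tryptic_digest(truth$polyprotein, max_missed = 0L)
  masses <- vapply(peps$seq[nchar(peps$seq) >= 5][1:200], peptide_mass,
                   numeric(1))
  set.seed(99)
  noisy <- masses * (1 + rnorm(length(masses), 0, 20e-6))
  err <- abs(noisy - masses) / masses * 1e6
  expect_gt(mean(err <= 75), 0.99)
})

test_that("alignment simulation is seeded JC evolution along the tree", {
  tr <- random_topology(6, seed = 2)
  a0 <- simulate_alignment(tr, 200L, rate = 0, seed = 1)
  expect_length(unique(a0$sequences), 1L)
  expect_true(all(p_distance(a0) == 0))

  a1 <- simulate_alignment(tr, 500L, rate = 1, seed = 7)
  a2 <- simulate_alignment(tr, 500L, rate = 1, seed = 7)
  expect_identical(a1$sequences, a2$sequences)
  expect_gt(max(p_distance(a1)), 0)
})

test_that("the full pipeline recovers planted maps across consecutive seeds", {
  ok <- vapply(401:420, function(s) recovers_truth(s, noiseless = TRUE),
               logical(1))
  expect_equal(mean(ok), 1.0)
})

test_that("synthetic bundles round-trip through the file formats", {
  truth <- generate_truth(seed = 5)
  reads <- simulate_edman(truth, seed = 5)
  peaks <- simulate_pmf(truth, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_bundle(truth, reads, peaks, dir)
  g <- read_sequences(paths[["genome"]])[[1]]
  expect_identical(g$sequence, truth$genome$sequence)
  r <- read_edman_tsv(paths[["reads"]])
  expect_identical(vapply(r, `[[`, character(1), "residues"),
                   vapply(reads, `[[`, character(1), "residues"))
  p <- read_peak_lists(paths[["peaks"]])
  expect_equal(p[[1]]$masses, peaks[[1]]$masses, tolerance = 1e-9)
})
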