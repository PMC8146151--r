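test_that("published cleavage positions partition the structural region", {
  set.seed(101)
  poly <- polyprotein_record("LJV-like", random_peptide(3047))
  ev <- evidence_set(region_end = 1113L,
                     fixed_positions = c(171L, 408L, 432L, 856L))
  map <- assemble_map(poly, ev)
  p <- map$proteins
  expect_equal(nrow(p), 5L)
  expect_equal(p$start, c(1L, 172L, 409L, 433L, 857L))
  expect_equal(p$end, c(171L, 408L, 432L, 856L, 1113L))
  expect_equal(map$boundaries, c(171L, 408L, 432L, 856L))
  # traditional weight-ranking names in the canonical gene order
  expect_equal(p$name, c("L", "VP2", "VP4", "VP1", "VP3"))
  # partition invariants
  expect_equal(p$start[-1L], utils::head(p$end, -1L) + 1L)
  expect_equal(length(map$boundaries), nrow(p) - 1L)
})

test_that("a bare region end yields a single flagged segment", {
  set.seed(7)
  poly <- polyprotein_record("p", random_peptide(300))
  map <- assemble_map(poly, evidence_set(region_end = 300L))
  expect_equal(nrow(map$proteins), 1L)
  expect_equal(map$proteins$start, 1L)
  expect_equal(map$proteins$end, 300L)
  expect_gt(length(map$notes), 0L)
})

test_that("planted maps are recovered exactly from synthetic evidence", {
  for (seed in 301:315) {
    expect_true(recovers_truth(seed, noiseless = TRUE),
                label = paste("noiseless seed", seed))
  }
})

test_that("anchored boundaries stay put when consistent anchors are added", {
  sc <- make_scenario(55, noiseless = TRUE, edman_segs = c(2L, 4L))
  map1 <- assemble_map(sc$poly, sc$evidence)
  sc2 <- make_scenario(55, noiseless = TRUE, edman_segs = c(2L, 3L, 4L))
  map2 <- assemble_map(sc2$poly, sc2$evidence)
  common <- intersect(sc$evidence$anchors$implied_cleavage_after,
                      map1$boundaries)
  expect_true(all(common %in% map2$boundaries))
  expect_equal(map1$boundaries, map2$boundaries)
})

test_that("segment weights sum to the region weight plus released water", {
  sc <- make_scenario(77, noiseless = TRUE)
  map <- assemble_map(sc$poly, sc$evidence)
  region_mw <- protein_average_mw(substr(sc$poly$sequence, 1,
                                         sc$truth$region_end))
  n <- nrow(map$proteins)
  expect_equal(sum(map$proteins$calc_mw_kda),
               region_mw + (n - 1) * 0.018015286, tolerance = 1e-6)
})

test_that("contradictory anchor/coverage evidence raises a named conflict", {
  # a protein whose tryptic peptides are all detected: positions inside the
  # third fragment are covered by the fragment itself plus both of its
  # missed-cleavage extensions (three independent peptides)
  prot <- paste0("ACDEFGHK", "ILMNPQSK", "TVWYADEK", "FGHILMNK", "QSTVWYAK")
  poly <- polyprotein_record("p", prot)
  peps <- tryptic_digest(prot, max_missed = 1L)
  masses <- vapply(peps$seq, peptide_mass, numeric(1))
  cfg <- pmf_config(min_peptide_mass = 0, max_peptide_mass = 1e9)
  res <- match_peaks(peak_list("s1", masses), list(p = prot), cfg)$p
  mid <- 20L  # inside fragment 3 (residues 17..24), away from cut points
  fake <- data.frame(spot_id = "fake", start = mid + 1L,
                     implied_cleavage_after = mid, mismatches = 0L,
                     ambiguous = FALSE)
  ev <- evidence_set(anchors = fake, pmf_results = list(res),
                     region_end = nchar(prot))
  expect_error(assemble_map(poly, ev),
               paste0("contradictory evidence.*", mid))
})

test_that("differing spot weights on one N-terminus propose an internal cut", {
  sc <- make_scenario(21, noiseless = TRUE)
  truth <- sc$truth
  poly <- sc$poly
  seg <- 4L
  pro_start <- truth$segments$start[seg]
  pro_end <- truth$segments$end[seg]
  cut_true <- pro_start + floor((pro_end - pro_start) * 0.6)
  mw_small <- protein_average_mw(substr(poly$sequence, pro_start, cut_true))
  mw_full <- protein_average_mw(substr(poly$sequence, pro_start, pro_end))
  anchors <- data.frame(spot_id = c("V1", "V2"),
                        start = pro_start,
                        implied_cleavage_after = pro_start - 1L,
                        mismatches = 0L, ambiguous = FALSE)
  obs <- data.frame(spot_id = c("V1", "V2"),
                    apparent_mw_kda = c(mw_small, mw_full))
  hyp <- infer_internal_processing(poly, pro_start, pro_end, anchors, obs)
  expect_false(is.null(hyp))
  expect_true(hyp$hypothesis)
  expect_lt(abs(hyp$position - cut_true), 3L)

  # single spot, or spots anchored at different positions: no hypothesis
  expect_null(infer_internal_processing(poly, pro_start, pro_end,
                                        anchors[1, ], obs[1, ]))
  anchors2 <- anchors
  anchors2$start[2] <- pro_start + 50L
  expect_null(infer_internal_processing(poly, pro_start, pro_end,
                                        anchors2, obs))
})

test_that("reports are deterministic and carry mat_peptide features", {
  set.seed(60)
  poly <- polyprotein_record("LJV-like", random_peptide(3047))
  ev <- evidence_set(region_end = 1113L,
                     fixed_positions = c(171L, 408L, 432L, 856L))
  map <- assemble_map(poly, ev)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_report(map, d1)
  p2 <- write_report(map, d2)
  gff <- readLines(p1[["gff"]])
  expect_equal(sum(grepl("\tmat_peptide\t", gff)), 5L)
  expect_false(any(grepl("WARNING", gff)))
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # genome-coordinate mode converts residue spans to nucleotide spans
  g <- genome_record("gnm", paste0(strrep("A", 918), "ATG",
                                   strrep("GGC", 3046), "TAA",
                                   strrep("T", 204)))
  orf <- orf_annotation(919L, 919L + 3L * 3048L - 1L)
  p3 <- write_report(map, withr::local_tempdir(), genome = g, orf = orf)
  gff3 <- readLines(p3[["gff"]])
  row1 <- strsplit(grep("\tmat_peptide\t", gff3, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(row1[4]), 919L)
  expect_equal(as.integer(row1[5]), 919L + 3L * 171L - 1L)
})
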