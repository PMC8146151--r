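test_that("p-distance counts differing sites with gap handling", {
  aln <- alignment_block(c("a", "b"), c("AAAA", "AAAT"))
  d <- p_distance(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "a"], 0)

  aln2 <- alignment_block(c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(p_distance(aln2)["a", "b"], 0)

  # pairwise vs complete deletion differ in which columns are compared
  aln3 <- alignment_block(c("a", "b", "c"),
                          c("A-GT", "ACGT", "ACGA"))
  dp <- p_distance(aln3, "pairwise")
  dc <- p_distance(aln3, "complete")
  expect_equal(dp["a", "b"], 0)       # 3 comparable sites, all equal
  expect_equal(dc["a", "c"], 1 / 3)   # column 2 dropped globally
  expect_error(p_distance(alignment_block(c("a", "b"), c("--", "AA"))),
               "no comparable sites")
})

test_that("p-distance equals a naive per-pair column scan", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    L <- 60L
    seqs <- vapply(seq_len(n), function(k) {
      s <- sample(c("A", "C", "G", "T", "-"), L, replace = TRUE,
                  prob = c(0.23, 0.23, 0.23, 0.23, 0.08))
      paste(s, collapse = "")
    }, character(1))
    aln <- alignment_block(paste0("t", seq_len(n)), seqs)
    d <- try(p_distance(aln), silent = TRUE)
    if (inherits(d, "try-error")) next
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      expect_equal(d[a, b], oracle_pdist_pair(seqs[a], seqs[b]))
      expect_equal(d[a, b], d[b, a])
    }
  }
})

test_that("three taxa give the closed-form star branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
})

test_that("additive matrices are recovered exactly, matching ape", {
  for (seed in 1:30) {
    n <- sample(5:8, 1)
    gen <- random_topology(n, seed = seed)
    d <- tree_distances(gen)
    tr <- neighbor_joining(d)
    expect_true(same_topology(tr, gen), label = paste("topology seed", seed))
    # branch lengths: total tree length is preserved for additive input
    expect_equal(sum(tr$edge.length), sum(gen$edge.length), tolerance = 1e-8)
    expect_equal(attr(tr, "negative_deficit"), 0)
    # patristic distances reproduce the input matrix exactly
    expect_equal(tree_distances(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    # independent implementation agrees on the topology
    expect_true(same_topology(tr, ape::nj(d)))
  }
})

test_that("all-equal distances give a deterministic tie-broken tree", {
  d <- matrix(1, 5, 5) - diag(5)
  dimnames(d) <- list(letters[1:5], letters[1:5])
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("asymmetric input is rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  d3 <- matrix(c(0, 1, 2, 1.5, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d3), "symmetric")
})

test_that("bootstrap supports behave at the degenerate and strong limits", {
  # clearly separated clades: long internal edge, short terminal edges
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.5,(c:0.05,d:0.05):0.5);")
  tr <- ape::unroot(tr)
  aln <- simulate_alignment(tr, n_sites = 2000L, rate = 1, seed = 5L)
  bt <- bootstrap_support(aln, n_replicates = 100L, seed = 9L)
  expect_gte(max(attr(bt, "split_support")), 99)

  bt1 <- bootstrap_support(aln, n_replicates = 1L, seed = 3L)
  expect_true(all(attr(bt1, "split_support") %in% c(0, 100)))

  bt2a <- bootstrap_support(aln, n_replicates = 20L, seed = 11L)
  bt2b <- bootstrap_support(aln, n_replicates = 20L, seed = 11L)
  expect_identical(attr(bt2a, "split_support"), attr(bt2b, "split_support"))
})

test_that("supports are invariant to taxon input order for a fixed seed", {
  tr <- ape::unroot(ape::read.tree(
    text = "((a:0.1,b:0.1):0.4,(c:0.1,d:0.1):0.4);"))
  aln <- simulate_alignment(tr, n_sites = 500L, rate = 1, seed = 2L)
  perm <- c(3L, 1L, 4L, 2L)
  aln_perm <- alignment_block(aln$labels[perm], aln$sequences[perm])
  s1 <- attr(bootstrap_support(aln, 30L, seed = 4L), "split_support")
  s2 <- attr(bootstrap_support(aln_perm, 30L, seed = 4L), "split_support")
  expect_equal(s1[sort(names(s1))], s2[sort(names(s2))])
})

test_that("outgroup rooting and Newick output work on supported trees", {
  tr <- ape::unroot(ape::read.tree(
    text = "((a:0.1,b:0.1):0.3,(c:0.1,d:0.1):0.3);"))
  aln <- simulate_alignment(tr, n_sites = 800L, rate = 1, seed = 8L)
  bt <- bootstrap_support(aln, n_replicates = 25L, seed = 1L)
  rooted <- root_on_outgroup(bt, "d")
  expect_true(ape::is.rooted(rooted))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bt, nwk)
  reread <- ape::read.tree(nwk)
  expect_setequal(reread$tip.label, c("a", "b", "c", "d"))
  expect_error(root_on_outgroup(bt, "zz"), "not a tip")
})
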