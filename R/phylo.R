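# Distance-based phylogenetics: p-distance, neighbor joining (implemented
# from scratch; ape serves only as an independent cross-check in the test
# suite), and nonparametric bootstrap over alignment columns.

#' Alignment block
#'
#' @param labels Character vector of unique taxon labels.
#' @param sequences Character vector of aligned sequences (equal length, gap
#'   character `-`).
#' @return Object of class `alignment_block`.
#' @export
alignment_block <- function(labels, sequences) {
  stopifnot(length(labels) == length(sequences),
            !anyDuplicated(labels), length(labels) >= 2L)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length")
  structure(list(labels = as.character(labels),
                 sequences = toupper(sequences),
                 n_sites = lens[1L]),
            class = "alignment_block")
}

#' Read an aligned FASTA file into an alignment block
#'
#' @param path Aligned FASTA path.
#' @return An [alignment_block()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  alignment_block(sub("\\s.*$", "", names(set)),
                  as.character(set))
}

.aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(m) <- aln$labels
  m
}

#' Pairwise distances from an alignment
#'
#' p-distance (proportion of differing sites) with pairwise or complete gap
#' deletion, optionally Jukes-Cantor corrected
#' (`d = -3/4 log(1 - 4p/3)`).
#'
#' @param aln An [alignment_block()].
#' @param deletion `"pairwise"` (sites ungapped in both sequences of a pair)
#'   or `"complete"` (globally ungapped columns only).
#' @param model `"p"` (default) or `"jc"`.
#' @return Symmetric distance matrix with zero diagonal, labelled by taxa.
#' @export
p_distance <- function(aln, deletion = c("pairwise", "complete"),
                       model = c("p", "jc")) {
  deletion <- match.arg(deletion)
  model <- match.arg(model)
  m <- .aln_matrix(aln)
  if (deletion == "complete") {
    keep <- colSums(m == "-") == 0L
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      n_ok <- sum(ok)
      if (n_ok == 0L)
        stop("no comparable sites between '", aln$labels[i], "' and '",
             aln$labels[j], "'")
      p <- sum(m[i, ok] != m[j, ok]) / n_ok
      if (model == "jc") {
        if (p >= 0.75) stop("p-distance ", signif(p, 3), " between '",
                            aln$labels[i], "' and '", aln$labels[j],
                            "' is not Jukes-Cantor correctable")
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration under the Q-criterion with the standard
#' branch-length formulas. Negative branch lengths are clamped to zero (the
#' clamped deficit is recorded in the `negative_deficit` attribute). Ties in
#' the Q-criterion are broken deterministically by the lexicographically
#' smallest pair of cluster representatives (each cluster represented by its
#' alphabetically first leaf label).
#'
#' @param d Symmetric distance matrix with labelled rows/columns.
#' @return An unrooted tree of class `phylo` (ape-compatible).
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- colnames(d)
  n <- nrow(d)
  stopifnot(n >= 3L, !is.null(labels))

  n_leaf <- n
  # active clusters: node id (leaf 1..n, internal n+1..) and representative
  node_id <- seq_len(n)
  rep_lab <- labels
  D <- unname(d)
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric()
  next_node <- n_leaf + 1L
  deficit <- 0

  clamp <- function(v) {
    if (v < 0) { deficit <<- deficit - v; 0 } else v
  }

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      ab <- sort(c(rep_lab[ij[1L]], rep_lab[ij[2L]]))
      paste(ab, collapse = "\r")
    })
    sel <- cand[order(pair_key)[1L], ]
    i <- sel[1L]; j <- sel[2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    vi <- clamp(vi); vj <- clamp(vj)
    new_id <- next_node
    next_node <- next_node + 1L
    edges <- rbind(edges, c(new_id, node_id[i]), c(new_id, node_id[j]))
    lens <- c(lens, vi, vj)
    others <- setdiff(seq_len(m), c(i, j))
    newd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    node_id <- c(node_id[others], new_id)
    rep_lab <- c(rep_lab[others], min(rep_lab[c(i, j)]))
  }

  # final 3-cluster star: closed-form branch lengths
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  center <- next_node
  edges <- rbind(edges, c(center, node_id[1]), c(center, node_id[2]),
                 c(center, node_id[3]))
  lens <- c(lens, clamp(v1), clamp(v2), clamp(v3))

  tree <- .as_phylo(edges, lens, labels, center)
  attr(tree, "negative_deficit") <- deficit
  tree
}

# Build an ape-compatible phylo object: internal nodes renumbered
# n_leaf+1.. with the root (center) first.
.as_phylo <- function(edges, lens, labels, center) {
  n_leaf <- length(labels)
  internal <- sort(unique(edges[, 1L]))
  internal <- c(center, setdiff(internal, center))
  remap <- integer(max(edges))
  remap[seq_len(n_leaf)] <- seq_len(n_leaf)
  remap[internal] <- n_leaf + seq_along(internal)
  edge <- cbind(remap[edges[, 1L]], remap[edges[, 2L]])
  tree <- list(edge = edge, edge.length = lens, tip.label = labels,
               Nnode = length(internal))
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

# leaf bipartitions induced by internal edges, as canonical strings
.tree_splits <- function(tree) {
  n_leaf <- length(tree$tip.label)
  desc <- .descendant_tips(tree)
  root <- n_leaf + 1L
  internal_edges <- which(tree$edge[, 2L] > n_leaf)
  splits <- character()
  for (e in internal_edges) {
    side <- sort(tree$tip.label[desc[[tree$edge[e, 2L]]]])
    if (length(side) <= 1L || length(side) >= n_leaf - 1L) next  # trivial
    all_lab <- sort(tree$tip.label)
    other <- setdiff(all_lab, side)
    canon <- if (all_lab[1L] %in% side) other else side
    splits <- c(splits, paste(sort(canon), collapse = "|"))
  }
  unique(splits)
}

.descendant_tips <- function(tree) {
  n_leaf <- length(tree$tip.label)
  n_node <- n_leaf + tree$Nnode
  desc <- vector("list", n_node)
  for (i in seq_len(n_leaf)) desc[[i]] <- i
  edge <- tree$edge
  # postorder: children before parents
  ord <- rev(seq_len(nrow(edge)))
  repeat {
    done <- TRUE
    for (e in ord) {
      p <- edge[e, 1L]; c <- edge[e, 2L]
      if (!is.null(desc[[c]]) && !all(desc[[c]] %in% desc[[p]])) {
        desc[[p]] <- unique(c(desc[[p]], desc[[c]]))
        done <- FALSE
      }
    }
    if (done) break
  }
  desc
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' percentage of replicates containing the same leaf bipartition. Supports
#' are stored as internal-node labels (ape convention), so they appear at
#' the nodes when the tree is written to Newick.
#'
#' @param aln An [alignment_block()].
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed for column resampling.
#' @param deletion Gap handling for [p_distance()].
#' @param model Distance model for [p_distance()].
#' @return The full-data `phylo` tree with `node.label` holding supports in
#'   \[0, 100\] (root label empty) and an attribute `split_support`.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L, seed = 1L,
                              deletion = "pairwise", model = "p") {
  stopifnot(n_replicates >= 1L)
  full <- neighbor_joining(p_distance(aln, deletion, model))
  target <- .tree_splits(full)
  counts <- stats::setNames(numeric(length(target)), target)
  rng <- .seeded_rng(seed)
  m <- .aln_matrix(aln)
  for (b in seq_len(n_replicates)) {
    cols <- rng$rint(aln$n_sites, aln$n_sites)
    rep_aln <- alignment_block(aln$labels,
                               apply(m[, cols, drop = FALSE], 1L, paste,
                                     collapse = ""))
    rep_tree <- try(neighbor_joining(p_distance(rep_aln, deletion, model)),
                    silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    found <- .tree_splits(rep_tree)
    hit <- target %in% found
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_replicates
  # attach as node labels: map each internal node (except root) to its split
  n_leaf <- length(full$tip.label)
  desc <- .descendant_tips(full)
  node_lab <- rep("", full$Nnode)
  all_lab <- sort(full$tip.label)
  for (nd in (n_leaf + 2L):(n_leaf + full$Nnode)) {
    side <- sort(full$tip.label[desc[[nd]]])
    if (length(side) <= 1L || length(side) >= n_leaf - 1L) next
    other <- setdiff(all_lab, side)
    canon <- paste(sort(if (all_lab[1L] %in% side) other else side),
                   collapse = "|")
    if (canon %in% names(counts))
      node_lab[nd - n_leaf] <- format(round(support[[canon]], 1))
  }
  full$node.label <- node_lab
  attr(full, "split_support") <- support
  full
}

#' Root a tree on a named outgroup (display operation)
#'
#' @param tree A `phylo` tree.
#' @param outgroup Tip label to root on.
#' @return Rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` tree (supports, if present, are node labels).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
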