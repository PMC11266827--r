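# repnet: the comparative phylogenomic stage. Per-cluster matrices of
# observed/expected inter-sample edge counts (similarity relative to random
# mixing), inverse-similarity distances, hand-rolled neighbor joining with
# deterministic tie-breaking, and the consensus split network of the
# per-cluster trees.

#' Observed/expected inter-sample edge matrix of a cluster
#'
#' Under uniform random edge placement over the cluster's node pairs, the
#' expected number of edges between samples s and t is
#' `E * n_s * n_t / P` (and `E * n_s (n_s - 1) / 2 / P` within a sample),
#' where `n_s` are the cluster's per-sample node counts, `E` its edge count
#' and `P` the number of unordered node pairs. The ratio observed/expected
#' measures pairwise similarity between the samples' reads. The matrix is
#' flagged incomplete when a sample is absent from the cluster or any
#' off-diagonal ratio is zero.
#'
#' @param clusters a `repeat_clusters` object.
#' @param reads the clustered `read_set`.
#' @param hits the hit table the clustering was built from.
#' @param id cluster id.
#' @param samples the full ordered sample set (defaults to the samples seen
#'   in `reads`).
#' @return list `cluster_id`, `samples`, `observed`, `expected`, `obs_exp`
#'   (matrices), `complete`.
#' @export
observed_expected_matrix <- function(clusters, reads, hits, id,
                                     samples = NULL) {
  reads <- data.table::as.data.table(reads)
  samples <- samples %||% sort(unique(reads$sample))
  members <- clusters$membership[cluster_id == id, read_id]
  smap <- setNames(reads$sample, reads$id)
  n_s <- table(factor(smap[members], levels = samples))
  N <- length(members)
  sub <- hits[read_a %in% members & read_b %in% members]
  E <- nrow(sub)
  if (E == 0) stop("cluster has no edges")
  P <- N * (N - 1) / 2

  k <- length(samples)
  expected <- outer(as.numeric(n_s), as.numeric(n_s)) * E / P
  diag(expected) <- as.numeric(n_s) * (as.numeric(n_s) - 1) / 2 * E / P
  dimnames(expected) <- list(samples, samples)

  observed <- matrix(0, k, k, dimnames = list(samples, samples))
  sa <- smap[sub$read_a]; sb <- smap[sub$read_b]
  for (i in seq_len(E)) {
    observed[sa[i], sb[i]] <- observed[sa[i], sb[i]] + 1
    if (sa[i] != sb[i]) observed[sb[i], sa[i]] <- observed[sb[i], sa[i]] + 1
  }
  obs_exp <- ifelse(expected > 0, observed / expected, 0)
  off <- obs_exp[upper.tri(obs_exp)]
  complete <- all(n_s > 0) && all(off > 0)
  list(cluster_id = id, samples = samples, observed = observed,
       expected = expected, obs_exp = obs_exp, complete = complete)
}

#' Inverse-similarity distance matrix (or exclusion verdict)
#'
#' `d(i, j) = 1 / obs_exp(i, j)` for i != j, zero diagonal; incomplete
#' matrices (a sample missing from the cluster, or a zero pairwise value)
#' are excluded rather than transformed. Only off-diagonal similarity enters
#' the distances.
#'
#' @param m output of [observed_expected_matrix()].
#' @return a symmetric distance matrix, or an object of class
#'   `cluster_exclusion` when the matrix is incomplete.
#' @export
to_distance <- function(m) {
  if (!isTRUE(m$complete))
    return(structure(list(cluster_id = m$cluster_id, excluded = TRUE),
                     class = "cluster_exclusion"))
  d <- 1 / m$obs_exp
  diag(d) <- 0
  d
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Classical agglomerative neighbor joining: at each step the pair
#' minimizing `Q(i, j) = (n - 2) d(i, j) - r_i - r_j` is joined (ties go to
#' the lexicographically smallest label pair) with the standard
#' branch-length formulas; negative branch lengths are clamped to zero with
#' the deficit shifted to the sister branch. On an additive distance matrix
#' the reconstructed tree metric reproduces the input exactly.
#'
#' @param d symmetric distance matrix with row/column names, n >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  labs <- rownames(d)          # tie-break key per working node
  frag <- labs                 # newick fragment per working node
  D <- unname(d)

  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + abs(qmin) * 1e-12 + 1e-300, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(labs[cand[, 1]], labs[cand[, 2]]),
                 pmax(labs[cand[, 1]], labs[cand[, 2]]))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":",
                      fmt(bj), ")")
    newlab <- min(labs[i], labs[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2

    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    labs <- c(labs[keep], newlab)
    n <- n - 1
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- D[1, 2] - v1
  v3 <- D[1, 3] - v1
  v <- pmax(c(v1, v2, v3), 0)
  txt <- paste0("(", frag[1], ":", fmt(v[1]), ",", frag[2], ":", fmt(v[2]),
                ",", frag[3], ":", fmt(v[3]), ");")
  ape::read.tree(text = txt)
}

# canonical split representation: the side not containing the reference
# taxon (the alphabetically first tip), as a "|"-collapsed sorted label set
tree_split_table <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  nt <- length(tips)
  # a rooted binary tree carries the root split on two edges; unrooting
  # merges them (and sums their lengths) so every split is counted once
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  nn <- nt + tree$Nnode
  below <- vector("list", nn)
  for (t in seq_len(nt)) below[[t]] <- tree$tip.label[t]
  keys <- character(nrow(tree$edge))
  sizes <- integer(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    pa <- tree$edge[e, 1]
    side <- below[[ch]]
    below[[pa]] <- c(below[[pa]], side)
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) == 0 || length(side) == nt) { keys[e] <- NA; next }
    side <- sort(side)
    keys[e] <- paste(side, collapse = "|")
    sizes[e] <- length(side)
  }
  ok <- !is.na(keys)
  data.table::data.table(split = keys[ok], size = sizes[ok],
                         weight = (tree$edge.length %||%
                                   rep(NA_real_, nrow(tree$edge)))[ok])
}

#' Consensus split network of a set of trees
#'
#' Decomposes each tree into its bipartitions (splits), retains splits whose
#' support (fraction of input trees containing the split) reaches
#' `min_support`, and weights each retained split by its mean branch length
#' over the trees containing it. Trivial (single-taxon) splits are always
#' included. The result displays the conflict among the input trees, as a
#' split network does.
#'
#' @param trees list of `phylo` trees over one shared leaf set.
#' @param min_support minimum support fraction (default 0.1).
#' @return a `split_set`: data.table `split` (taxon labels joined by `|`,
#'   canonical side excluding the alphabetically first taxon), `size`,
#'   `support`, `weight`; attribute `taxa` holds the leaf set and `n_trees`
#'   the number of input trees.
#' @export
consensus_network <- function(trees, min_support = 0.1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1) stop("at least one tree required")
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), taxa))
      stop("trees have mismatched leaf sets")
  per <- data.table::rbindlist(lapply(trees, tree_split_table))
  agg <- per[, list(support = .N / length(trees),
                    weight = mean(weight), size = size[1]),
             by = split]
  keep <- agg[support >= min_support | size == 1 | size == length(taxa) - 1]
  data.table::setorder(keep, -support, split)
  out <- keep[, list(split, size, support, weight)]
  data.table::setattr(out, "taxa", taxa)
  data.table::setattr(out, "n_trees", length(trees))
  data.table::setattr(out, "class", c("split_set", class(out)))
  out[]
}

#' Does a split set contain a given bipartition?
#'
#' @param splits a `split_set`.
#' @param side character vector of taxon labels on one side of the split.
#' @param min_support minimum support to count as present.
#' @return logical.
#' @export
has_split <- function(splits, side, min_support = 0) {
  taxa <- attr(splits, "taxa")
  side <- sort(side)
  if (taxa[1] %in% side) side <- sort(setdiff(taxa, side))
  key <- paste(side, collapse = "|")
  any(splits$split == key & splits$support >= min_support)
}

#' Write a split set as a NEXUS splits block
#'
#' Emits a Taxa block plus a SplitsTree-style Splits block (weights and
#' confidences = support).
#'
#' @param splits a `split_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nexus_splits <- function(splits, path) {
  taxa <- attr(splits, "taxa")
  nt <- length(taxa)
  lines <- c("#NEXUS", "",
             "BEGIN Taxa;",
             sprintf("DIMENSIONS ntax=%d;", nt),
             "TAXLABELS",
             sprintf("[%d] '%s'", seq_len(nt), taxa),
             ";", "END;", "",
             "BEGIN Splits;",
             sprintf("DIMENSIONS ntax=%d nsplits=%d;", nt, nrow(splits)),
             "FORMAT labels=no weights=yes confidences=yes;",
             "MATRIX")
  rows <- vapply(seq_len(nrow(splits)), function(i) {
    side <- strsplit(splits$split[i], "|", fixed = TRUE)[[1]]
    idx <- match(side, taxa)
    sprintf("[%d] %.8g %.4f %s,", i,
            ifelse(is.na(splits$weight[i]), 1, splits$weight[i]),
            splits$support[i], paste(sort(idx), collapse = " "))
  }, "")
  writeLines(c(lines, rows, ";", "END;"), path)
  invisible(path)
}

#' Per-cluster NJ trees and their consensus network
#'
#' Runs [observed_expected_matrix()] and [to_distance()] for every supplied
#' cluster, drops excluded clusters, builds a neighbor-joining tree per
#' surviving cluster and returns the consensus split network with
#' bookkeeping (`clusters_retained + clusters_excluded` equals the number
#' of clusters given).
#'
#' @param clusters a `repeat_clusters` object.
#' @param reads the clustered `read_set`.
#' @param hits the hit table.
#' @param cluster_ids clusters to process (e.g. the top-size set).
#' @param samples ordered sample set.
#' @param min_support consensus support threshold.
#' @return list `trees` (named by cluster id), `network` (`split_set`),
#'   `retained`, `excluded` (cluster id vectors).
#' @export
repeat_network <- function(clusters, reads, hits, cluster_ids,
                           samples = NULL, min_support = 0.1) {
  trees <- list()
  excluded <- integer()
  for (id in cluster_ids) {
    m <- observed_expected_matrix(clusters, reads, hits, id, samples)
    d <- to_distance(m)
    if (inherits(d, "cluster_exclusion") || nrow(as.matrix(d)) < 3) {
      excluded <- c(excluded, id)
    } else {
      trees[[as.character(id)]] <- neighbor_joining(d)
    }
  }
  network <- if (length(trees)) consensus_network(trees, min_support)
             else NULL
  list(trees = trees, network = network,
       retained = as.integer(names(trees)), excluded = excluded)
}
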