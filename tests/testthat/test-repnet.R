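# helper: fake clustered dataset with prescribed edges between two samples
edge_dataset <- function(n_per_sample = 50, edges) {
  ids <- c(paste0("AAAA_", 1:n_per_sample), paste0("BBBB_", 1:n_per_sample))
  rs <- data.table::data.table(
    id = ids, sequence = "A", sample = substr(ids, 1, 4),
    mate = 1L, pair_index = seq_along(ids), origin = NA_character_)
  mem <- data.table::data.table(read_id = ids, cluster_id = 1L)
  cl <- fake_clusters(mem, length(ids))
  hits <- data.table::data.table(read_a = ids[edges[, 1]],
                                 read_b = ids[edges[, 2]],
                                 overlap = 101L, matches = 101L,
                                 identity = 1, orientation = "same",
                                 offset = 0L)
  list(reads = rs, cl = cl, hits = hits)
}

test_that("uniform random edges give obs/exp near 1 in every cell", {
  n <- 50
  draw_mat <- function(seed) {
    with_seed(seed, {
      pool <- t(utils::combn(2 * n, 2))
      pick <- pool[sample.int(nrow(pool), 500), , drop = FALSE]
      d <- edge_dataset(n, pick)
      observed_expected_matrix(d$cl, d$reads, d$hits, 1)$obs_exp
    })
  }
  m <- draw_mat(1)
  # permutation oracle: SD of each cell under repeated uniform placement
  sims <- simplify2array(lapply(2:201, draw_mat))
  sds <- apply(sims, c(1, 2), stats::sd)
  expect_true(all(abs(m - 1) < 3 * sds))
})

test_that("within-sample-only edges give zero inter-sample ratio, incomplete", {
  within <- cbind(1:25, 26:50)  # all edges inside sample AAAA
  d <- edge_dataset(50, within)
  m <- observed_expected_matrix(d$cl, d$reads, d$hits, 1)
  expect_equal(m$obs_exp["AAAA", "BBBB"], 0)
  expect_false(m$complete)
  expect_s3_class(to_distance(m), "cluster_exclusion")
})

test_that("a sample absent from the cluster marks the matrix incomplete", {
  d <- edge_dataset(50, cbind(1:10, 11:20))
  m <- observed_expected_matrix(d$cl, d$reads, d$hits, 1,
                                samples = c("AAAA", "BBBB", "CCCC"))
  expect_false(m$complete)
})

test_that("distances are inverse similarities with zero diagonal", {
  m <- list(cluster_id = 1L, samples = c("a", "b"),
            obs_exp = matrix(c(1, 2, 2, 1), 2, dimnames =
                               list(c("a", "b"), c("a", "b"))),
            complete = TRUE)
  d <- to_distance(m)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(diag(d), c(a = 0, b = 0))
  m$obs_exp[1, 2] <- m$obs_exp[2, 1] <- 1
  expect_equal(to_distance(m)["a", "b"], 1)
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reproduces additive tree metrics exactly", {
  for (seed in 1:10) {
    tr <- with_seed(seed, ape::rtree(8, br = function(n) runif(n, 0.1, 1)))
    tr <- ape::unroot(tr)
    D <- ape::cophenetic.phylo(tr)
    ord <- sort(rownames(D))
    D <- D[ord, ord]
    rec <- neighbor_joining(D)
    D2 <- ape::cophenetic.phylo(rec)[ord, ord]
    expect_lt(max(abs(D - D2)), 1e-9)
    # independent cross-check: same topology as the reference NJ in ape
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(rec),
                                           ape::unroot(ape::nj(D)))), 0)
  }
})

test_that("Q-matrix ties break deterministically toward the smallest labels", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # A and B are joined first: they share a parent node (form a cherry)
  parent_of <- function(tree, tip)
    tree$edge[tree$edge[, 2] == match(tip, tree$tip.label), 1]
  expect_equal(parent_of(t1, "A"), parent_of(t1, "B"))
})

test_that("consensus network aggregates splits with support and weight", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  net1 <- consensus_network(rep(list(t1), 10))
  expect_true(all(net1$support == 1))
  expect_equal(nrow(net1), 5)  # 4 trivial + 1 internal split
  expect_true(has_split(net1, c("C", "D")))

  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  net <- consensus_network(c(rep(list(t1), 5), rep(list(t2), 5)),
                           min_support = 0.1)
  # both incompatible internal splits retained at support 0.5
  internal <- net[net$size == 2]
  expect_equal(nrow(internal), 2)
  expect_equal(internal$support, c(0.5, 0.5))
  net6 <- consensus_network(c(rep(list(t1), 5), rep(list(t2), 5)),
                            min_support = 0.6)
  expect_equal(nrow(net6[net6$size == 2]), 0)

  t3 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(consensus_network(list(t1, t3)), "mismatched")
})

test_that("the nexus splits block is well formed", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  net <- consensus_network(rep(list(t1), 3))
  f <- tempfile(fileext = ".nex")
  write_nexus_splits(net, f)
  lines <- readLines(f)
  expect_equal(lines[1], "#NEXUS")
  expect_true(any(grepl("BEGIN Splits;", lines)))
  expect_true(any(grepl(sprintf("nsplits=%d", nrow(net)), lines)))
})

test_that("exclusion bookkeeping partitions the processed clusters", {
  # cluster 1: balanced cross-sample edges; cluster 2: within-sample only
  n <- 10
  ids <- c(paste0("AAAA_", 1:20), paste0("BBBB_", 1:20), paste0("CCCC_", 1:20))
  rs <- data.table::data.table(id = ids, sequence = "A",
                               sample = substr(ids, 1, 4), mate = 1L,
                               pair_index = seq_along(ids),
                               origin = NA_character_)
  mem <- data.table::data.table(
    read_id = ids, cluster_id = rep(rep(1:2, each = 10), 3))
  cl <- fake_clusters(mem, length(ids))
  in1 <- mem[cluster_id == 1, read_id]
  in2 <- mem[cluster_id == 2, read_id]
  hits <- rbind(
    data.table::data.table(read_a = rep(in1, each = 3),
                           read_b = rep(in1, 3)),
    data.table::data.table(read_a = in2[1:9], read_b = in2[2:10]))
  hits <- hits[read_a != read_b]
  hits[, c("overlap", "matches", "identity", "orientation", "offset") :=
         list(101L, 101L, 1, "same", 0L)]
  net <- repeat_network(cl, rs, hits, 1:2)
  expect_equal(sort(c(net$retained, net$excluded)), 1:2)
  expect_equal(net$excluded, 2L)
})
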