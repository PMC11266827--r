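test_that("elementary overlap geometries are reported correctly", {
  a <- with_seed(1, random_dna(101))
  # identical reads: full-length hit, same orientation
  h <- find_similarity_hits(c(r1 = a, r2 = a))
  expect_equal(nrow(h), 1)
  expect_equal(h$overlap, 101)
  expect_equal(h$identity, 1)
  expect_equal(h$orientation, "same")
  # reverse complement: strand closure
  h2 <- find_similarity_hits(c(r1 = a, r2 = revcomp(a)))
  expect_equal(nrow(h2), 1)
  expect_equal(h2$orientation, "reverse")
  expect_equal(h2$identity, 1)
})

test_that("the 90%/55 identity contract is enforced over the overlap", {
  set.seed(42)
  a <- random_dna(101)
  make_b <- function(n_mm) {
    # B's first 60 bp overlap A's last 60 bp, with n_mm planted mismatches
    ov <- strsplit(substr(a, 42, 101), "")[[1]]
    pos <- seq(3, by = 8, length.out = n_mm)  # spread, no seed-killing runs
    ov[pos] <- vapply(ov[pos], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste0(paste(ov, collapse = ""), random_dna(41))
  }
  h3 <- find_similarity_hits(c(A = a, B = make_b(3)))
  expect_equal(nrow(h3), 1)
  expect_equal(h3$overlap, 60)
  expect_equal(h3$identity, 57 / 60)
  h7 <- find_similarity_hits(c(A = a, B = make_b(7)))
  expect_equal(nrow(h7), 0)  # 53/60 < 0.90
})

test_that("hit set is invariant to read order and global reverse complement", {
  g <- with_seed(11, {
    bp <- genome_blueprint(20000, list(
      repeat_family("f", "LTR-Gypsy", 1000, 8, divergence = 0.02)))
    make_polyploid(list(simulate_monoploid(bp, seed = 4)))
  })
  rs <- skim_reads(g, coverage = 0.4, seed = 5, sample_code = "AAAA")
  seqs <- setNames(rs$sequence, rs$id)
  key <- function(h) sort(paste(pmin(h$read_a, h$read_b),
                                pmax(h$read_a, h$read_b), h$overlap))
  h <- find_similarity_hits(seqs)
  h_perm <- find_similarity_hits(rev(seqs))
  expect_setequal(key(h), key(h_perm))
  h_rc <- find_similarity_hits(setNames(revcomp(seqs), names(seqs)))
  expect_setequal(key(h), key(h_rc))
  expect_equal(sort(table(h$orientation)), sort(table(h_rc$orientation)))
})

test_that("seeded finder equals the brute-force scan on mixed reads", {
  g <- with_seed(21, {
    bp <- genome_blueprint(30000, list(
      repeat_family("f1", "LTR-Gypsy", 800, 10, divergence = 0.04),
      repeat_family("s1", "satellite", 150, 40, divergence = 0.03,
                    tandem = TRUE)))
    make_polyploid(list(simulate_monoploid(bp, seed = 6)))
  })
  rs <- skim_reads(g, coverage = 0.2, seed = 7, sample_code = "AAAA")
  seqs <- setNames(rs$sequence, rs$id)[1:80]
  s <- find_similarity_hits(seqs)
  b <- brute_force_hits(seqs)
  data.table::setorder(s, read_a, read_b)
  data.table::setorder(b, read_a, read_b)
  expect_equal(s, b, ignore_attr = TRUE)
})

test_that("guaranteed seed length follows the pigeonhole bound", {
  expect_equal(guaranteed_seed_k(0.90, 55, 101), 8)
  expect_equal(guaranteed_seed_k(1.00, 55, 101), 55)   # exact matches only
  # hand enumeration: the minimum is attained around L = 60 (3 mismatches
  # allowed), ceil(57 / 4) = 15
  expect_equal(guaranteed_seed_k(0.95, 55, 101), 15)
})

test_that("organelle k-mer filter discards matching pairs and keeps pairing", {
  ref <- with_seed(31, random_dna(10000))
  plastome_read <- substr(ref, 501, 601)
  clean <- with_seed(32, random_dna(101))
  # exactly one shared 24-mer: the next base breaks the reference run
  off_base <- setdiff(c("A", "C", "G", "T"), substr(ref, 1025, 1025))[1]
  one_kmer <- paste0(substr(ref, 1001, 1024), off_base,
                     with_seed(33, random_dna(76)))
  rs <- make_read_set(c(plastome_read, clean, one_kmer, clean, clean, clean))
  out <- filter_organelle(rs, ref)
  # pair 1 removed (mate 1 is a plastome substring), pairs 2 and 3 kept
  expect_equal(attr(out, "discarded_pairs"), 1)
  expect_equal(unique(out$pair_index), c(2L, 3L))
  expect_equal(nrow(out), 4)
  expect_error(filter_organelle(rs, ref, k = 200), "read length")
  expect_error(filter_organelle(rs, ""), "empty")
})

test_that("random reads are essentially never discarded by the filter", {
  ref <- with_seed(41, random_dna(10000))
  rs <- make_read_set(with_seed(42, replicate(1000, random_dna(101))))
  out <- filter_organelle(rs, ref)
  expect_equal(attr(out, "discarded_pairs"), 0)
  expect_equal(nrow(out), 1000)
})

test_that("clustering partitions the non-singleton graph by component", {
  # edgeless graph: everything unclustered
  seqs <- with_seed(51, replicate(10, random_dna(101)))
  names(seqs) <- paste0("r", 1:10)
  empty_hits <- find_similarity_hits(seqs)
  cl0 <- cluster_reads(seqs, empty_hits)
  expect_equal(nrow(cl0$clusters), 0)
  expect_equal(length(cl0$unclustered), 10)

  # complete graph of identical reads: one cluster of 50
  same <- setNames(rep(with_seed(52, random_dna(101)), 50), paste0("s", 1:50))
  cl1 <- cluster_reads(same, find_similarity_hits(same))
  expect_equal(cl1$clusters$n_reads, 50)
  expect_equal(length(cl1$unclustered), 0)
})

test_that("two planted zero-divergence families give two provenance-pure clusters", {
  g <- with_seed(61, {
    bp <- genome_blueprint(70000, list(
      repeat_family("famX", "LTR-Gypsy", 500, 60, divergence = 0),
      repeat_family("famY", "LTR-Copia", 500, 60, divergence = 0)))
    make_polyploid(list(simulate_monoploid(bp, seed = 8)))
  })
  rs <- skim_reads(g, coverage = 0.5, seed = 9, sample_code = "AAAA",
                   error_rate = 0)
  rs <- rs[rs$origin != "background"]
  cl <- cluster_reads(rs, find_similarity_hits(rs))
  expect_equal(nrow(cl$clusters), 2)
  prov <- merge(cl$membership,
                data.table::data.table(read_id = rs$id, origin = rs$origin),
                by = "read_id")
  purity <- prov[, list(p = max(table(origin)) / .N), by = cluster_id]
  expect_true(all(purity$p == 1))
})

test_that("top-cluster filter applies the size-fraction threshold", {
  # the threshold is strict ("more than 0.01%"): a 10-read cluster of
  # 100,000 sits exactly on it and is dropped
  tab <- data.table::data.table(cluster_id = 1:3, n_reads = c(500L, 10L, 9L),
                                size_fraction = c(500, 10, 9) / 100000)
  expect_equal(filter_top_clusters(tab, 1e-4)$cluster_id, 1L)
  expect_equal(nrow(filter_top_clusters(tab, 0)), 3)
  tab2 <- data.table::data.table(cluster_id = 1:2, n_reads = c(11L, 9L),
                                 size_fraction = c(11, 9) / 100000)
  expect_equal(filter_top_clusters(tab2, 1e-4)$cluster_id, 1L)
})

test_that("hitsort and membership TSVs round-trip", {
  seqs <- setNames(rep(with_seed(71, random_dna(101)), 3), paste0("r", 1:3))
  h <- find_similarity_hits(seqs)
  f <- tempfile(fileext = ".tsv")
  write_hitsort(h, f)
  h2 <- read_hitsort(f)
  expect_equal(h2$read_a, h$read_a)
  expect_equal(h2$identity, h$identity)
  cl <- cluster_reads(seqs, h)
  f2 <- tempfile(fileext = ".tsv")
  write_cluster_membership(cl, f2)
  expect_equal(nrow(data.table::fread(f2)), 3)
})
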