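test_that("planted lengths and proportions are exactly additive", {
  bp <- genome_blueprint(100000, list(
    repeat_family("fam", "LTR-Gypsy", 1000, 10, divergence = 0)))
  m <- simulate_monoploid(bp, seed = 1)
  expect_equal(m$length, 110000)
  expect_equal(m$truth$bases, 10000)
  g <- make_polyploid(list(m))
  expect_equal(g$truth$proportion, 10000 / 110000)

  empty <- simulate_monoploid(genome_blueprint(5000), seed = 2)
  expect_equal(empty$length, 5000)
  expect_equal(nrow(empty$truth), 0)
  expect_equal(nrow(empty$features), 0)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(repeat_family("x", "LTR-Gypsy", 10, 1), "monomer_length")
  expect_error(repeat_family("x", "LTR-Gypsy", 100, 1, divergence = 0.3),
               "divergence")
  expect_error(five_s_unit(strrep("A", 50), "ACGT"), "gene")
  expect_error(with_seed(1, random_five_s(5)), "variants")
  expect_error(genome_spec("TOOLONG", list(genome_blueprint(100))),
               "4 characters")
  expect_error(genome_spec("ABCD", list(genome_blueprint(100)), nx = 2),
               "nx")
  bp <- genome_blueprint(1000, list(
    repeat_family("fat", "LTR-Gypsy", 500, 10)))
  expect_error(simulate_monoploid(bp, seed = 1), "sizing error")
})

test_that("planted copies diverge from the consensus at the requested rate", {
  div <- 0.05
  bp <- genome_blueprint(100000, list(
    repeat_family("fam", "LTR-Gypsy", 500, 50, divergence = div)))
  m <- simulate_monoploid(bp, seed = 7)
  cons <- strsplit(m$consensus[["fam"]], "")[[1]]
  ident <- vapply(seq_len(nrow(m$features)), function(i) {
    cp <- strsplit(substr(m$sequence, m$features$start[i],
                          m$features$end[i]), "")[[1]]
    mean(cp == cons)
  }, numeric(1))
  # mean copy-vs-consensus identity within 3 SD of 1 - divergence
  se <- sqrt(div * (1 - div) / 500 / 50)
  expect_lt(abs(mean(ident) - (1 - div)), 3 * se)
})

test_that("polyploid union preserves bases and dilutes proportions", {
  bpA <- genome_blueprint(100000, list(
    repeat_family("X", "LTR-Gypsy", 1000, 10)))
  bpB <- genome_blueprint(100000, list(
    repeat_family("Y", "LTR-Copia", 1000, 20)))
  mA <- simulate_monoploid(bpA, seed = 1)
  mB <- simulate_monoploid(bpB, seed = 2)
  g <- make_polyploid(list(mA, mB))
  expect_equal(g$length, mA$length + mB$length)
  pX_mono <- mA$truth$bases / mA$length
  pX_holo <- g$truth[g$truth$family == "X", proportion]
  expect_equal(pX_holo, mA$truth$bases / g$length)
  expect_lt(pX_holo, pX_mono)
  # identical subgenomes leave proportions unchanged
  g2 <- make_polyploid(list(mA, mA))
  expect_equal(g2$truth[g2$truth$family == "X", proportion], pX_mono)
  # base-count conservation: proportion x holoploid length = planted bases
  expect_equal(g$truth$proportion * g$length, g$truth$bases)
  expect_error(make_polyploid(list()), "empty")
})

test_that("distinct IGS variants per subgenome give the ribotype count", {
  gene <- with_seed(3, random_dna(120))
  fsA <- with_seed(4, random_five_s(1, gene = gene, array_copies = 10))
  fsB <- with_seed(5, random_five_s(1, gene = gene, array_copies = 10))
  mA <- simulate_monoploid(genome_blueprint(20000, five_s = fsA), seed = 1)
  mB <- simulate_monoploid(genome_blueprint(20000, five_s = fsB), seed = 2)
  expect_equal(make_polyploid(list(mA, mB))$ribotype_count, 2)
  expect_equal(make_polyploid(list(mA, mA))$ribotype_count, 1)
})

test_that("skim read counts, pairing and headers follow the contract", {
  genome <- strrep("ACGT", 2500000)  # 10 Mbp
  rs <- skim_reads(genome, coverage = 0.1, seed = 3, sample_code = "AAAA",
                   error_rate = 0)
  expect_equal(nrow(rs), 2 * floor(0.1 * 1e7 / 202))  # 4950 pairs
  expect_true(all(substr(rs$id, 1, 4) == "AAAA"))
  expect_true(all(grepl("/[12]$", rs$id)))
  expect_equal(rs$mate, rep(1:2, nrow(rs) / 2))
  expect_true(all(nchar(rs$sequence) == 101))

  expect_error(skim_reads(genome, coverage = 0, seed = 1,
                          sample_code = "AAAA"), "coverage")
  expect_error(skim_reads(genome, coverage = 0.6, seed = 1,
                          sample_code = "AAAA"), "coverage")
  expect_error(skim_reads(strrep("A", 200), coverage = 0.5, seed = 1,
                          sample_code = "AAAA"), "shorter")
})

test_that("error-free reads are exact genome substrings (either strand)", {
  genome <- with_seed(9, random_dna(20000))
  rs <- skim_reads(genome, coverage = 0.3, seed = 10, sample_code = "BBBB",
                   error_rate = 0)
  found <- vapply(rs$sequence, function(s)
    grepl(s, genome, fixed = TRUE) || grepl(revcomp(s), genome, fixed = TRUE),
    logical(1))
  expect_true(all(found))
})

test_that("identical spec and seed give byte-identical output", {
  spec <- genome_spec("CCCC", list(genome_blueprint(30000, list(
    repeat_family("f", "satellite", 300, 20, divergence = 0.02,
                  tandem = TRUE)))), seed = 99)
  run <- function() {
    g <- simulate_genome(spec)
    skim_reads(g, coverage = 0.2, seed = 123)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_reads_fasta(r1, f1); write_reads_fasta(r2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  q1 <- tempfile()
  write_reads_fastq(r1, q1)
  lines <- readLines(q1)
  expect_equal(length(lines), 4 * nrow(r1))
  expect_true(all(lines[seq(4, length(lines), 4)] == strrep("I", 101)))
})

test_that("read sampling reproduces planted proportions within 3 binomial SD", {
  bp <- genome_blueprint(750000, list(
    repeat_family("fam", "LTR-Gypsy", 1000, 125, divergence = 0.01)))
  g <- make_polyploid(list(simulate_monoploid(bp, seed = 5)))
  rs <- skim_reads(g, coverage = 0.5, seed = 6, sample_code = "DDDD")
  expect_gte(nrow(rs) / 2, 2000)
  p <- g$truth$proportion
  frac <- mean(rs$origin == "fam")
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / nrow(rs)))
})

test_that("consensus evolution along a tree tracks branch lengths", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cons <- with_seed(8, random_dna(5000))
  tips <- with_seed(9, evolve_consensus(cons, tree, rate = 0.02))
  dd <- function(x, y) mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  # sisters are ~2 branch units apart, cross-cherry pairs ~4 units
  expect_lt(dd(tips[["A"]], tips[["B"]]), dd(tips[["A"]], tips[["C"]]))
  expect_lt(abs(dd(tips[["A"]], tips[["B"]]) - 0.04), 0.015)
})
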