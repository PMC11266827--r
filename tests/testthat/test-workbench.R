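test_that("interleaving alternates mates in pair order", {
  m1 <- make_read_set(c("ACGT", "CCCC", "GGGG"), mates = c(1L, 1L, 1L))
  m2 <- make_read_set(c("TTTT", "AAAA", "CGCG"), mates = c(1L, 1L, 1L))
  m2$id <- m1$id  # matching pair ids
  out <- interleave_pairs(m1, m2)
  expect_equal(nrow(out), 6)
  expect_equal(out$mate, rep(1:2, 3))
  expect_equal(out$sequence, c("ACGT", "TTTT", "CCCC", "AAAA", "GGGG", "CGCG"))
  expect_error(interleave_pairs(m1, m2[1:2]), "orphan")
  m3 <- data.table::copy(m2); m3$id <- paste0("X", m3$id)
  expect_error(interleave_pairs(m1, m3), "orphan")
})

test_that("fastq input round-trips to fasta with identical sequences", {
  g <- with_seed(1, random_dna(5000))
  rs <- skim_reads(g, coverage = 0.3, seed = 2, sample_code = "QQQQ")
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(rs, fq)
  back <- read_reads(fq)
  expect_equal(back$sequence, rs$sequence)
  expect_equal(back$sample, rs$sample)
  expect_equal(back$mate, rs$mate)
  fa <- tempfile(fileext = ".fasta")
  write_reads_fasta(back, fa)
  again <- read_reads(fa)
  expect_equal(again$sequence, rs$sequence)
})

test_that("length filter truncates and drops short pairs", {
  rs <- make_read_set(c(strrep("A", 101), strrep("C", 101),   # intact pair
                        strrep("G", 90), strrep("T", 101),    # short mate
                        strrep("A", 120), strrep("C", 130)))  # long pair
  out <- length_filter(rs, 101L)
  expect_equal(unique(out$pair_index), c(1L, 3L))
  expect_true(all(nchar(out$sequence) == 101))
  expect_equal(substr(out[out$pair_index == 3L & out$mate == 1L]$sequence,
                      1, 3), "AAA")
})

test_that("pipeline configuration validates and round-trips through YAML", {
  expect_error(pipeline_config(), "specs or read_files")
  cfg <- pipeline_config(read_files = "reads.fasta", coverage = 0.2,
                         min_identity = 0.92, min_overlap = 60,
                         seed = 5L)
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  for (field in c("read_files", "coverage", "min_identity", "min_overlap",
                  "size_threshold", "seed"))
    expect_equal(cfg2[[field]], cfg[[field]], label = field)
})

toy_specs <- function() {
  shared <- with_seed(7, replicate(3, random_dna(1200)))
  gene <- with_seed(8, random_dna(120))
  lapply(1:3, function(i) {
    fams <- lapply(1:3, function(j)
      repeat_family(paste0("fam", j),
                    c("LTR-Gypsy", "LTR-Copia", "satellite")[j],
                    1200, 15, divergence = 0.02, consensus = shared[j],
                    tandem = j == 3))
    genome_spec(paste0("S", i, "AA"),
                list(genome_blueprint(80000, fams,
                                      five_s = with_seed(20 + i,
                                        random_five_s(1, gene = gene,
                                                      array_copies = 20)))),
                seed = 500 + i)
  })
}

test_that("the full pipeline runs, logs counts and writes artifacts", {
  shared <- with_seed(7, replicate(3, random_dna(1200)))
  gene <- with_seed(8, random_dna(120))
  lib <- data.table::data.table(
    sequence = c(shared, gene),
    lineage = c("Retand", "SIRE", "satellite", "rDNA-5S"))
  out1 <- file.path(tempdir(), "pipe1")
  cfg <- pipeline_config(specs = toy_specs(), coverage = 0.25,
                         library = lib, five_s_gene = gene,
                         genome_sizes = data.table::data.table(
                           sample = c("S1AA", "S2AA", "S3AA"),
                           two_C_pg = c(0.2, 0.3, 0.4), nx = c(2L, 2L, 2L)),
                         seed = 77L, output_dir = out1)
  res <- run_pipeline(cfg, quiet = TRUE)
  expect_gt(res$log$n_hits, 0)
  expect_gt(res$log$n_clusters, 0)
  expect_equal(res$log$reads_in, res$log$analysed_reads)
  expect_true(all(c("hitsort.tsv", "clusters.tsv", "abundance.tsv",
                    "pipeline_log.yaml") %in% list.files(out1)))
  expect_true(!is.null(res$abundance))
  expect_true(!is.null(res$network))
  expect_equal(res$log$clusters_retained + res$log$clusters_excluded,
               res$log$n_top_clusters)
  # annotation recovered the planted lineages among the top clusters
  expect_true(all(c("Retand", "SIRE", "satellite") %in%
                    res$annotations$lineage))
})

test_that("fixed seed makes pipeline outputs byte-identical", {
  out1 <- file.path(tempdir(), "det1")
  out2 <- file.path(tempdir(), "det2")
  base <- function(out) pipeline_config(
    specs = toy_specs()[1:2], coverage = 0.2, seed = 99L, output_dir = out)
  r1 <- run_pipeline(base(out1), quiet = TRUE)
  r2 <- run_pipeline(base(out2), quiet = TRUE)
  for (f in c("hitsort.tsv", "clusters.tsv"))
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
})

test_that("a single-sample run reports the Hs/Ho error and still completes", {
  lib <- data.table::data.table(
    sequence = with_seed(7, replicate(3, random_dna(1200))),
    lineage = c("Retand", "SIRE", "satellite"))
  cfg <- pipeline_config(specs = toy_specs()[1], coverage = 0.2,
                         library = lib, seed = 101L)
  res <- run_pipeline(cfg, quiet = TRUE)
  expect_match(res$hs_ho_error, "single-sample")
  expect_null(res[["hs_ho"]])  # exact name: $ would partial-match the error
  expect_true(!is.null(res$abundance))
})
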