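# Bundled benchmark scenarios: fully seeded synthetic study conditions with
# planted ground truth, used to score the pipeline end to end (and shared by
# the package's tests and reproduction script so both exercise the exact
# same conditions).

#' Seeded/brute-force hit-finder equivalence check
#'
#' Simulates a small skim read set over a genome with two planted families
#' plus background, runs both the seeded hit finder and the brute-force
#' all-offset scan under the standard contract, and reports whether the two
#' hit tables agree exactly.
#'
#' @param seed integer seed.
#' @param n_reads number of reads compared (default 200).
#' @return list `seeded`, `brute` (hit tables), `equal` (logical),
#'   `n_reads`.
#' @export
scenario_oracle_equivalence <- function(seed = 1L, n_reads = 200L) {
  g <- with_seed(seed, {
    bp <- genome_blueprint(60000, list(
      repeat_family("famA", "LTR-Gypsy", 2000, 10, divergence = 0.03),
      repeat_family("famB", "satellite", 270, 60, divergence = 0.02,
                    tandem = TRUE)))
    make_polyploid(list(simulate_monoploid(bp, seed = derive_seed(seed, "m"))))
  })
  reads <- skim_reads(g, coverage = 0.3, seed = derive_seed(seed, "r"),
                      sample_code = "ORAC")
  reads <- reads[seq_len(min(n_reads, nrow(reads)))]
  seeded <- find_similarity_hits(reads)
  brute <- brute_force_hits(reads)
  ord <- function(h) h[order(read_a, read_b)]
  list(seeded = seeded, brute = brute,
       equal = isTRUE(all.equal(ord(seeded), ord(brute),
                                check.attributes = FALSE)),
       n_reads = nrow(reads))
}

#' Planted-proportion recovery on a three-sample skim dataset
#'
#' Three samples with ~10 Mbp monoploid genomes, five planted families
#' spanning ~1-25% of the genome (two LTR-Gypsy, one LTR-Copia, one tandem
#' satellite, one DNA transposon; copy divergence 2-4%), skimmed at 0.1x
#' coverage. The full pipeline (hits, clusters, top filter, annotation
#' against the planted consensus library, quantification) is run and each
#' estimated per-sample family proportion is compared with planted truth as
#' a binomial z-score on the analysed read count.
#'
#' @param seed integer seed.
#' @return list `scores` (data.table: sample, family, truth, estimate, z),
#'   `max_abs_z`, `abundance`, `analysed`, `n_reads`.
#' @export
scenario_planted_proportions <- function(seed = 42L) {
  fams <- function() list(
    repeat_family("famA", "LTR-Gypsy", 6000, 417, divergence = 0.03),
    repeat_family("famB", "LTR-Copia", 5000, 200, divergence = 0.03),
    repeat_family("famC", "LTR-Gypsy", 3000, 167, divergence = 0.04),
    repeat_family("famD", "satellite", 270, 740, divergence = 0.02,
                  tandem = TRUE),
    repeat_family("famE", "DNA-transposon", 1000, 100, divergence = 0.02))
  codes <- c("S1AA", "S2AA", "S3AA")
  genomes <- lapply(codes, function(cd)
    simulate_genome(genome_spec(cd, list(genome_blueprint(5.7e6, fams())),
                                seed = derive_seed(seed, cd))))
  reads <- data.table::rbindlist(lapply(genomes, function(g)
    skim_reads(g, coverage = 0.1,
               seed = derive_seed(seed, paste0("sk", g$sample_code)))))
  hits <- find_similarity_hits(reads)
  cl <- cluster_reads(reads, hits)
  top <- filter_top_clusters(cl, 1e-4)
  lib <- data.table::rbindlist(lapply(genomes, function(g)
    data.table::data.table(sequence = unname(g$consensus),
                           lineage = names(g$consensus))))
  ann <- annotate_clusters(cl, reads, lib)
  analysed <- data.table::as.data.table(reads)[, list(n_reads = .N),
                                               by = sample]
  gs <- data.table::data.table(sample = codes, monoploid_mbp = 10L)
  ab <- quantify_repeats(cl, ann, reads, analysed, gs,
                         cluster_ids = top$cluster_id)
  scores <- data.table::rbindlist(lapply(seq_along(codes), function(i) {
    tr <- genomes[[i]]$truth
    data.table::rbindlist(lapply(tr$family, function(f) {
      p <- tr[family == f, proportion]
      est <- ab[ab$sample == codes[i] & ab$lineage == f, proportion]
      if (length(est) == 0) est <- 0
      n <- analysed[analysed$sample == codes[i], n_reads]
      data.table::data.table(sample = codes[i], family = f, truth = p,
                             estimate = est,
                             z = (est - p) / sqrt(p * (1 - p) / n))
    }))
  }))
  list(scores = scores, max_abs_z = max(abs(scores$z)), abundance = ab,
       analysed = analysed, n_reads = nrow(reads))
}

#' One seeded 5S graph-typing simulation
#'
#' A single sample carrying `n_ribotypes` 5S arrays (shared conserved gene,
#' independent random spacers, 60 units each) in random background is
#' skimmed at 0.3x; the planted 5S reads are typed with
#' [classify_5s_graph()].
#'
#' @param n_ribotypes planted ribotype count (1-3).
#' @param seed integer seed.
#' @return the recovered graph type (integer).
#' @export
scenario_five_s_typing <- function(n_ribotypes, seed = 1L) {
  with_seed(seed, {
    gene <- random_dna(120)
    fs <- random_five_s(n_ribotypes, gene = gene, array_copies = 60)
    bp <- genome_blueprint(90000, five_s = fs)
    g <- make_polyploid(list(simulate_monoploid(bp,
                                                seed = derive_seed(seed, "m"))))
    rs <- skim_reads(g, coverage = 0.3, seed = derive_seed(seed, "s"),
                     sample_code = "FIVE")
    classify_5s_graph(rs[rs$origin == "5S"], gene)$graph_type
  })
}

#' Hs/Ho landscape on a conserved vs diverged two-sample dataset
#'
#' Two equal-coverage samples carry a "conserved" lineage (four independent
#' 2 kb families with identical consensus in both samples, 1% copy
#' divergence) and a "diverged" lineage (four families whose consensus
#' accumulated ~8% pairwise divergence between the samples, 4% per branch,
#' with 3.5% copy divergence), so within-sample read pairs stay below the
#' 10% mismatch limit of the hit contract while between-sample pairs mostly
#' exceed it. Several independent families per lineage average out the
#' window-level heterogeneity of fixed consensus divergence, and the
#' records of `n_replicates` replicate simulations are pooled into one
#' histogram per lineage before taking the mode.
#'
#' @param seed integer seed.
#' @param n_replicates replicate datasets pooled (default 2).
#' @return list `modes` (data.table from [landscape_histograms()]),
#'   `records`, `n_reads`.
#' @export
scenario_hs_ho <- function(seed = 11L, n_replicates = 2L) {
  one <- function(seed) {
    with_seed(seed, {
      nf <- 4
      cons_c <- replicate(nf, random_dna(2000))
      cons_d <- replicate(nf, random_dna(2000))
      tipA <- vapply(cons_d, function(s) mutate_seq(s, 0.04), "")
      tipB <- vapply(cons_d, function(s) mutate_seq(s, 0.04), "")
      mk <- function(code, dcons, seed2) {
        fams <- c(
          lapply(1:nf, function(i)
            repeat_family(paste0("cons", i), "LTR-Gypsy", 2000, 40,
                          divergence = 0.01, consensus = cons_c[i])),
          lapply(1:nf, function(i)
            repeat_family(paste0("div", i), "LTR-Copia", 2000, 40,
                          divergence = 0.035, consensus = dcons[i])))
        bp <- genome_blueprint(700000, fams)
        g <- make_polyploid(list(simulate_monoploid(bp, seed = seed2)))
        skim_reads(g, coverage = 0.4, seed = derive_seed(seed2, "sk"),
                   sample_code = code)
      }
      reads <- rbind(mk("AAAA", tipA, derive_seed(seed, "A")),
                     mk("BBBB", tipB, derive_seed(seed, "B")))
      hits <- find_similarity_hits(reads)
      cl <- cluster_reads(reads, hits)
      lib <- data.table::data.table(
        sequence = c(cons_c, tipA, tipB),
        lineage = c(rep("conserved", nf), rep("diverged", 2 * nf)))
      ann <- annotate_clusters(cl, reads, lib)
      analysed <- data.table::as.data.table(reads)[, list(n_reads = .N),
                                                   by = sample]
      hs_ho(hits, reads, cl, ann, analysed)
    })
  }
  recs <- lapply(seq_len(n_replicates), function(i)
    one(derive_seed(seed, paste0("rep", i))))
  rec <- data.table::rbindlist(recs)
  lh <- landscape_histograms(rec)
  list(modes = lh$modes, records = rec, n_reads = NA_integer_)
}

#' End-to-end consensus-network recovery of a known species tree
#'
#' Six samples diverge along a fixed 6-leaf species tree (unit terminal
#' branches, internal edges of length 2-3 units, 0.8% substitutions per
#' unit): twelve 1.5 kb repeat families evolve along the tree, every tip
#' genome plants 20 copies of each tip consensus (1% copy divergence), and
#' each sample is skimmed at 0.3x. The full pipeline then builds per-cluster
#' observed/expected matrices, inverse distances, NJ trees and their
#' consensus network, which is checked for the three internal splits of the
#' true tree.
#'
#' @param seed integer seed.
#' @return list `recovered` (named logical for the three internal splits),
#'   `all_recovered`, `n_trees`, `n_excluded`, `network`, `n_reads`.
#' @export
scenario_species_network <- function(seed = 1L) {
  species_tree <- ape::read.tree(
    text = "((S1AA:1,S2AA:1):2,S3AA:3,((S4AA:1,S5AA:1):2,S6AA:3):2);")
  with_seed(seed, {
    n_fam <- 12
    anc <- replicate(n_fam, random_dna(1500))
    tips <- lapply(seq_len(n_fam), function(i)
      evolve_consensus(anc[i], species_tree, rate = 0.008))
    codes <- species_tree$tip.label
    reads <- data.table::rbindlist(lapply(codes, function(cd) {
      fams <- lapply(seq_len(n_fam), function(i)
        repeat_family(paste0("fam", i), "LTR-Gypsy", 1500, 20,
                      divergence = 0.01, consensus = tips[[i]][[cd]]))
      bp <- genome_blueprint(450000, fams)
      g <- make_polyploid(list(simulate_monoploid(bp,
                                                  seed = derive_seed(seed, cd))))
      skim_reads(g, coverage = 0.3,
                 seed = derive_seed(seed, paste0("s", cd)), sample_code = cd)
    }))
    hits <- find_similarity_hits(reads)
    cl <- cluster_reads(reads, hits)
    top <- filter_top_clusters(cl, 0.001)
    net <- repeat_network(cl, reads, hits, top$cluster_id,
                          samples = sort(codes), min_support = 0.1)
    recovered <- c(
      S1_S2 = has_split(net$network, c("S1AA", "S2AA"), 0.5),
      S4_S5 = has_split(net$network, c("S4AA", "S5AA"), 0.5),
      S4_S5_S6 = has_split(net$network, c("S4AA", "S5AA", "S6AA"), 0.5))
    list(recovered = recovered, all_recovered = all(recovered),
         n_trees = length(net$trees), n_excluded = length(net$excluded),
         network = net$network, n_reads = nrow(reads))
  })
}
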