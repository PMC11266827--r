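# workbench: format I/O shims, pre-processing, configuration and the
# end-to-end pipeline driver. Every stage logs machine-readable counts so
# the read/cluster bookkeeping the analysis depends on stays auditable.

#' Read a FASTA/FASTQ file into a read_set
#'
#' The format is taken from the file's first character (`>` FASTA, `@`
#' FASTQ). Mate numbers are parsed from `/1` `/2` id suffixes; the sample
#' code is the first 4 characters of the id unless supplied.
#'
#' @param path input file.
#' @param sample_code optional 4-character code overriding the id prefix.
#' @return a `read_set` data.table.
#' @export
read_reads <- function(path, sample_code = NULL) {
  first <- substr(readLines(path, n = 1L), 1, 1)
  fmt <- if (first == "@") "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  ids <- sub("\\s.*$", "", names(ss))
  mate <- ifelse(grepl("/2$", ids), 2L, 1L)
  reads <- data.table::data.table(
    id = ids, sequence = as.character(ss),
    sample = if (is.null(sample_code)) substr(ids, 1, 4) else sample_code,
    mate = mate,
    pair_index = cumsum(mate == 1L),
    origin = NA_character_)
  data.table::setattr(reads, "class",
                      c("read_set", class(data.table::data.table())))
  reads
}

#' Interleave two mate read sets
#'
#' Produces the alternating `/1`, `/2` record order (a1, a2, b1, b2, ...)
#' expected by interleaved-pair FASTA input; ids must correspond pairwise.
#'
#' @param mates1,mates2 `read_set`s (or files read with [read_reads()]) of
#'   first and second mates, same length and order.
#' @return interleaved `read_set`.
#' @export
interleave_pairs <- function(mates1, mates2) {
  if (is.character(mates1)) mates1 <- read_reads(mates1)
  if (is.character(mates2)) mates2 <- read_reads(mates2)
  if (nrow(mates1) != nrow(mates2))
    stop("orphan mates: files differ in read count")
  base1 <- sub("/[12]$", "", mates1$id)
  base2 <- sub("/[12]$", "", mates2$id)
  if (!all(base1 == base2)) stop("orphan mates: ids do not match pairwise")
  n <- nrow(mates1)
  out <- data.table::data.table(
    id = as.vector(rbind(paste0(base1, "/1"), paste0(base2, "/2"))),
    sequence = as.vector(rbind(mates1$sequence, mates2$sequence)),
    sample = rep(mates1$sample, each = 2L),
    mate = rep(1:2, n),
    pair_index = rep(seq_len(n), each = 2L),
    origin = NA_character_)
  data.table::setattr(out, "class",
                      c("read_set", class(data.table::data.table())))
  out
}

#' Fixed-length filter for read pairs
#'
#' Keeps pairs in which both mates are at least `length` bp, truncating
#' longer mates to exactly `length` (a pass-through stand-in for
#' quality trimming on simulated clean reads).
#'
#' @param reads a `read_set`.
#' @param length target read length (default 101).
#' @return filtered `read_set`.
#' @export
length_filter <- function(reads, length = 101L) {
  keylen <- data.table::as.data.table(reads)[, list(
    ok = all(nchar(sequence) >= length)), by = list(sample, pair_index)]
  out <- merge(data.table::as.data.table(reads), keylen,
               by = c("sample", "pair_index"))
  out <- out[ok == TRUE]
  out[, sequence := substr(sequence, 1L, length)]
  out[, ok := NULL]
  data.table::setorder(out, sample, pair_index, mate)
  data.table::setcolorder(out, names(reads))
  data.table::setattr(out, "class",
                      c("read_set", class(data.table::data.table())))
  out[]
}

#' Pipeline configuration
#'
#' Collects every tunable of the skim-to-network pipeline with the standard
#' defaults (90% similarity, 55 bp minimum overlap, 0.01% cluster size
#' threshold, 24-mer/2-match organelle filter, 2 x 101 bp reads).
#'
#' @param specs list of [genome_spec()]s to simulate (alternative to
#'   `read_files`).
#' @param read_files character vector of FASTA/FASTQ paths.
#' @param coverage skim coverage for simulation, in (0, 0.5].
#' @param read_length,insert_range,error_rate read simulation parameters.
#' @param min_identity,min_overlap similarity contract.
#' @param size_threshold top-cluster size fraction threshold.
#' @param organelle optional organelle reference sequences (or FASTA path).
#' @param organelle_k,organelle_min_matches organelle filter settings.
#' @param library optional repeat library data.frame (`sequence`,
#'   `lineage`) or FASTA path with `lineage` parsed from `name#lineage`
#'   headers.
#' @param five_s_gene optional conserved 5S gene exemplar for graph typing.
#' @param genome_sizes optional data.table `sample`, `two_C_pg`, `nx`.
#' @param min_support consensus network support threshold.
#' @param refine,modularity_threshold community refinement settings.
#' @param seed master seed.
#' @param output_dir optional directory for TSV/newick/nexus outputs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(specs = NULL, read_files = NULL, coverage = 0.1,
                            read_length = 101L,
                            insert_range = c(123L, 329L), error_rate = 0.005,
                            min_identity = 0.90, min_overlap = 55L,
                            size_threshold = 1e-4, organelle = NULL,
                            organelle_k = 24L, organelle_min_matches = 2L,
                            library = NULL, five_s_gene = NULL,
                            genome_sizes = NULL, min_support = 0.1,
                            refine = FALSE, modularity_threshold = 0.4,
                            seed = 1L, output_dir = NULL) {
  if (is.null(specs) && is.null(read_files))
    stop("either specs or read_files must be given")
  stopifnot(coverage > 0, coverage <= 0.5,
            min_identity > 0, min_identity <= 1, min_overlap >= 1,
            size_threshold >= 0, min_support >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Serialize / load a pipeline configuration as YAML
#'
#' Simulation specs and in-memory tables are not serialized; file-based
#' fields round-trip losslessly.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @return `path` / the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  flat <- config[!vapply(config, is.function, logical(1))]
  flat$specs <- NULL
  flat$library <- if (is.character(config$library)) config$library
  flat$genome_sizes <- NULL
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

read_library <- function(library) {
  if (is.character(library) && length(library) == 1 && file.exists(library)) {
    ss <- Biostrings::readDNAStringSet(library)
    parts <- strsplit(names(ss), "#", fixed = TRUE)
    data.table::data.table(
      name = vapply(parts, `[`, "", 1),
      lineage = vapply(parts, function(p) p[length(p)], ""),
      sequence = as.character(ss))
  } else {
    data.table::as.data.table(library)
  }
}

#' Run the full skim-to-network pipeline
#'
#' Stages: simulate or load reads, length filter, optional organelle
#' filter, similarity hits, clustering, top-cluster filter, annotation and
#' quantification (with a repeat library), tandem/5S profiling of tandem
#' clusters, Hs/Ho landscape (>= 2 samples), per-cluster observed/expected
#' matrices, NJ trees and the consensus network (>= 3 samples), and
#' genome-size statistics. Each stage appends its counts to `$log`; a fixed
#' seed makes the whole bundle reproducible.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return a result bundle (list); see element names.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  res <- list(config = config)

  # --- reads -------------------------------------------------------------
  if (!is.null(config$specs)) {
    truth <- list()
    reads <- list()
    for (spec in config$specs) {
      g <- simulate_genome(spec)
      truth[[spec$sample_code]] <- g$truth
      reads[[spec$sample_code]] <- skim_reads(
        g, coverage = config$coverage, read_length = config$read_length,
        insert_range = config$insert_range, error_rate = config$error_rate,
        seed = derive_seed(config$seed, paste0("skim_", spec$sample_code)))
    }
    reads <- data.table::rbindlist(reads)
    data.table::setattr(reads, "class",
                        c("read_set", class(data.table::data.table())))
    res$truth <- truth
  } else {
    reads <- data.table::rbindlist(lapply(config$read_files, read_reads))
    data.table::setattr(reads, "class",
                        c("read_set", class(data.table::data.table())))
  }
  log$reads_in <- nrow(reads)
  say("reads", log$reads_in, " reads from ",
      length(unique(reads$sample)), " samples")

  # --- pre-processing ----------------------------------------------------
  reads <- length_filter(reads, config$read_length)
  log$after_length_filter <- nrow(reads)
  if (!is.null(config$organelle)) {
    org <- config$organelle
    if (is.character(org) && length(org) == 1 && file.exists(org))
      org <- as.character(Biostrings::readDNAStringSet(org))
    reads <- filter_organelle(reads, org, config$organelle_k,
                              config$organelle_min_matches)
    log$organelle_discarded_pairs <- attr(reads, "discarded_pairs")
  }
  log$analysed_reads <- nrow(reads)
  analysed <- data.table::as.data.table(reads)[, list(n_reads = .N),
                                               by = sample]
  res$reads <- reads
  res$analysed <- analysed
  say("preprocess", log$analysed_reads, " reads analysed")

  # --- similarity graph and clusters -------------------------------------
  hits <- find_similarity_hits(reads, config$min_identity,
                               config$min_overlap)
  log$n_hits <- nrow(hits)
  say("hits", log$n_hits, " similarity hits")
  clusters <- cluster_reads(reads, hits, refine = config$refine,
                            modularity_threshold = config$modularity_threshold)
  log$n_clusters <- nrow(clusters$clusters)
  log$n_unclustered <- length(clusters$unclustered)
  top <- filter_top_clusters(clusters, config$size_threshold)
  log$n_top_clusters <- nrow(top)
  say("clusters", log$n_clusters, " clusters, ", log$n_top_clusters,
      " above size threshold")
  res$hits <- hits
  res$clusters <- clusters
  res$top_clusters <- top

  # --- annotation and quantification -------------------------------------
  gs <- config$genome_sizes
  if (!is.null(gs)) {
    gs <- genome_size_table(gs$sample, gs$two_C_pg, gs$nx)
  } else {
    gs <- data.table::data.table(sample = analysed$sample,
                                 monoploid_mbp = NA_integer_)
  }
  res$genome_sizes <- gs
  if (!is.null(config$library)) {
    lib <- read_library(config$library)
    ann <- annotate_clusters(clusters, reads, lib)
    res$annotations <- ann
    res$abundance <- quantify_repeats(clusters, ann, reads, analysed, gs,
                                      cluster_ids = top$cluster_id)
    say("annotate", nrow(ann), " clusters annotated")

    tandem_ids <- ann[lineage %in% c("rDNA-5S", "satellite") &
                        cluster_id %in% top$cluster_id, cluster_id]
    profiles <- list()
    for (id in tandem_ids) {
      members <- clusters$membership[cluster_id == id, read_id]
      rr <- data.table::as.data.table(reads)[id %in% members]
      gene <- if (identical(ann[cluster_id == id, lineage], "rDNA-5S"))
        config$five_s_gene else NULL
      prof <- tandem_profile(rr, subgraph = cluster_subgraph(clusters, id),
                             gene = gene,
                             genome_proportion =
                               clusters$clusters[cluster_id == id,
                                                 size_fraction])
      prof[, cluster_id := id]
      profiles[[as.character(id)]] <- prof
    }
    if (length(profiles)) res$tandem_profiles <-
        data.table::rbindlist(profiles, fill = TRUE)
    say("tandem", length(profiles), " tandem clusters profiled")

    # Hs/Ho landscape needs at least two samples
    if (nrow(analysed) >= 2) {
      res$hs_ho <- hs_ho(hits, reads, clusters, ann, analysed)
      res$landscape <- landscape_histograms(res$hs_ho)
      say("hsho", nrow(res$hs_ho), " Hs/Ho records")
    } else {
      res$hs_ho_error <- "Hs/Ho is undefined for a single-sample dataset"
      say("hsho", "skipped: ", res$hs_ho_error)
    }
  }

  # --- phylogenomic network ----------------------------------------------
  if (nrow(analysed) >= 3 && nrow(top) > 0) {
    net <- repeat_network(clusters, reads, hits, top$cluster_id,
                          samples = sort(analysed$sample),
                          min_support = config$min_support)
    res$network <- net
    log$clusters_retained <- length(net$retained)
    log$clusters_excluded <- length(net$excluded)
    say("network", log$clusters_retained, " trees, ",
        log$clusters_excluded, " clusters excluded")
  }

  # --- statistics ---------------------------------------------------------
  if (!is.null(res$abundance) && !all(is.na(gs$monoploid_mbp)) &&
      nrow(analysed) >= 3) {
    res$size_stats <- tryCatch(
      repeat_size_stats(res$abundance, gs),
      error = function(e) NULL)
  }

  res$log <- log

  # --- outputs ------------------------------------------------------------
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$output_dir, f)
    write_hitsort(hits, p("hitsort.tsv"))
    write_cluster_membership(clusters, p("clusters.tsv"))
    if (!is.null(res$abundance)) write_abundance_tsv(res$abundance,
                                                     p("abundance.tsv"))
    if (!is.null(res$tandem_profiles))
      data.table::fwrite(res$tandem_profiles, p("tandem_profiles.tsv"),
                         sep = "\t")
    if (!is.null(res$network) && length(res$network$trees)) {
      ape::write.tree(do.call(c, res$network$trees), p("nj_trees.nwk"))
      write_nexus_splits(res$network$network, p("consensus_network.nex"))
    }
    if (!is.null(res$size_stats))
      data.table::fwrite(res$size_stats, p("size_stats.tsv"), sep = "\t")
    yaml::write_yaml(log, p("pipeline_log.yaml"))
  }
  res
}
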