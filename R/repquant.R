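# repquant: cluster annotation against a labelled repeat library and the
# genome-size arithmetic that turns cluster sizes into genome proportions,
# Mbp amounts per monoploid genome (1Cx), and fold ratios.

#' Monoploid genome size (1Cx) from 2C and ploidy
#'
#' The 2C nucleus carries `nx` monoploid complements, so 1Cx = 2C / nx
#' (equivalently, C divided by the number of genome copies: C/2 for 4x,
#' C/3 for 6x), rounded half-up to 3 decimals as genome-size tables print.
#'
#' @param two_C_pg 2C genome size in pg (> 0).
#' @param nx ploidy (>= 1).
#' @return 1Cx in pg, rounded to 3 decimals.
#' @export
monoploid_size <- function(two_C_pg, nx) {
  if (any(two_C_pg <= 0)) stop("two_C_pg must be positive")
  if (any(nx < 1)) stop("nx must be >= 1")
  # half-up at 3 decimals; the 1e-9 guard keeps exact .0005 boundaries
  # (e.g. 0.713 / 2 = 0.3565) from dropping below .5 in floating point
  floor(two_C_pg / nx * 1000 + 0.5 + 1e-9) / 1000
}

#' Convert pg of DNA to integer Mbp
#'
#' Uses 978 Mbp/pg, truncating to whole Mbp.
#'
#' @param pg DNA amount in pg (> 0).
#' @return integer Mbp.
#' @export
pg_to_mbp <- function(pg) {
  if (any(pg <= 0)) stop("pg must be positive")
  as.integer(floor(pg * 978 + 1e-9))
}

#' Fold ratio rounded to one decimal
#'
#' @param a,b positive numbers (`b > 0`).
#' @return `round(a / b, 1)`.
#' @export
fold_ratio <- function(a, b) {
  if (any(b == 0)) stop("division by zero")
  floor(a / b * 10 + 0.5 + 1e-9) / 10
}

#' Assemble a genome-size record table
#'
#' Derives 1Cx (pg), holoploid Mbp (from 2C) and monoploid Mbp per sample.
#' Mbp values truncate at each conversion step: holoploid_mbp =
#' floor(2C * 978), monoploid_mbp = floor(holoploid_mbp / nx).
#'
#' @param sample sample codes.
#' @param two_C_pg 2C genome sizes (pg).
#' @param nx ploidies.
#' @return data.table with `sample`, `two_C_pg`, `nx`, `one_Cx_pg`,
#'   `holoploid_mbp`, `monoploid_mbp`.
#' @export
genome_size_table <- function(sample, two_C_pg, nx) {
  holo <- pg_to_mbp(two_C_pg)
  data.table::data.table(
    sample = sample, two_C_pg = two_C_pg, nx = as.integer(nx),
    one_Cx_pg = monoploid_size(two_C_pg, nx),
    holoploid_mbp = holo,
    monoploid_mbp = as.integer(floor(holo / nx)))
}

#' Read a genome-size sample table (TSV)
#'
#' Expects at least columns `sample`, `two_C_pg`, `nx` (extra columns such
#' as chromosome number or a printed 1Cx column are kept).
#'
#' @param path TSV path.
#' @return data.table with derived columns appended as in
#'   [genome_size_table()].
#' @export
read_genome_size_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("sample", "two_C_pg", "nx") %in% names(tab)))
  derived <- genome_size_table(tab$sample, tab$two_C_pg, tab$nx)
  cbind(tab, derived[, -(1:3)])
}

#' Annotate clusters against a labelled repeat library
#'
#' Each read votes for the lineage with which it shares the most k-mers
#' (both strands); reads with no library match abstain. A cluster is
#' assigned the plurality lineage when the winning vote fraction (over
#' voting reads) reaches `min_vote`, else `Unclassified`.
#'
#' @param clusters a `repeat_clusters` object.
#' @param reads the `read_set` clustered.
#' @param library data.frame with columns `sequence` and `lineage`.
#' @param k k-mer size for voting (default 13).
#' @param min_vote minimum winning vote fraction (default 0.5).
#' @return data.table `cluster_id`, `lineage`, `vote_fraction`, `n_voting`.
#' @export
annotate_clusters <- function(clusters, reads, library, k = 13L,
                              min_vote = 0.5) {
  if (is.null(library) || nrow(library) == 0) stop("empty repeat library")
  lineages <- sort(unique(library$lineage))
  reads <- data.table::as.data.table(reads)
  mm <- merge(clusters$membership,
              reads[, list(read_id = id, sequence)], by = "read_id")
  votes <- cpp_kmer_votes(mm$sequence, library$sequence,
                          match(library$lineage, lineages) - 1L,
                          length(lineages), as.integer(k))
  best <- max.col(votes, ties.method = "first")
  has <- votes[cbind(seq_len(nrow(votes)), best)] > 0L
  mm[, lineage := ifelse(has, lineages[best], NA_character_)]
  ann <- mm[, {
    v <- lineage[!is.na(lineage)]
    if (length(v) == 0) {
      list(lineage = "Unclassified", vote_fraction = 0, n_voting = 0L)
    } else {
      tab <- sort(table(v), decreasing = TRUE)
      frac <- as.numeric(tab[1]) / length(v)
      list(lineage = if (frac >= min_vote) names(tab)[1] else "Unclassified",
           vote_fraction = frac, n_voting = length(v))
    }
  }, by = cluster_id]
  data.table::setorder(ann, cluster_id)
  ann[]
}

#' Repeat abundance per sample and lineage
#'
#' proportion(sample, lineage) = reads of that sample in clusters of that
#' lineage / analysed reads of that sample; amount = proportion *
#' monoploid_mbp. An `"All repeats"` row sums the lineages per sample.
#'
#' @param clusters a `repeat_clusters` object (use the top-filtered cluster
#'   set by passing `cluster_ids`).
#' @param annotations output of [annotate_clusters()].
#' @param reads the clustered `read_set`.
#' @param analysed data.table `sample`, `n_reads`: reads entering clustering
#'   per sample (the proportion denominator).
#' @param genome_sizes data.table with `sample` and `monoploid_mbp` (see
#'   [genome_size_table()]).
#' @param cluster_ids optional cluster ids to include (e.g. from
#'   [filter_top_clusters()]); default all.
#' @return data.table `sample`, `lineage`, `n_reads`, `proportion`,
#'   `amount_mbp`, including the `"All repeats"` summary rows.
#' @export
quantify_repeats <- function(clusters, annotations, reads, analysed,
                             genome_sizes, cluster_ids = NULL) {
  counts <- cluster_sample_counts(clusters, reads)
  if (!is.null(cluster_ids)) counts <- counts[cluster_id %in% cluster_ids]
  if (!all(counts$sample %in% analysed$sample))
    stop("unknown sample code in clusters: ",
         paste(setdiff(counts$sample, analysed$sample), collapse = ", "))
  counts <- merge(counts, annotations[, list(cluster_id, lineage)],
                  by = "cluster_id")
  per <- counts[, list(n_reads = sum(n)), by = list(sample, lineage)]
  all_rep <- per[, list(lineage = "All repeats", n_reads = sum(n_reads)),
                 by = sample]
  per <- rbind(per, all_rep)
  per <- merge(per, analysed, by = "sample", suffixes = c("", ".analysed"))
  per[, proportion := n_reads / n_reads.analysed]
  per <- merge(per, genome_sizes[, list(sample, monoploid_mbp)], by = "sample")
  per[, amount_mbp := proportion * monoploid_mbp]
  out <- per[, list(sample, lineage, n_reads, proportion, amount_mbp)]
  data.table::setorder(out, sample, lineage)
  out[]
}

#' Write an abundance table as TSV
#'
#' @param abundance output of [quantify_repeats()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(abundance, path) {
  data.table::fwrite(abundance, path, sep = "\t")
  invisible(path)
}
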