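# divland: the Hs/Ho sequence-diversification landscape. For every read in
# an annotated cluster, the ratio of similarity hits to reads of the same
# sample (Hs) over coverage-normalized hits to reads of other samples (Ho)
# separates conserved repeat families (log ratio near 0) from families that
# diversified between samples (log ratio shifted positive).

#' Per-read intraspecific/interspecific hit ratios
#'
#' For each read of an annotated cluster, `Hs` counts its similarity-graph
#' edges to same-sample reads and `Ho_raw` its edges to other-sample reads.
#' `Ho_norm = Ho_raw * (n_same - 1) / n_other` (analysed read totals) makes
#' the two comparable under unequal per-sample coverage. Reads with
#' `Hs == 0` or `Ho_raw == 0` are excluded from the ratio records and
#' counted separately (attribute `excluded`), so sample-private repeats
#' remain visible.
#'
#' @param hits hit table from [find_similarity_hits()].
#' @param reads the clustered `read_set`.
#' @param clusters a `repeat_clusters` object.
#' @param annotations output of [annotate_clusters()].
#' @param analysed data.table `sample`, `n_reads` (analysed totals).
#' @return data.table `read_id`, `sample`, `lineage`, `Hs`, `Ho_raw`,
#'   `Ho_norm`, `log_ratio` (log10); attribute `excluded` is a data.table
#'   of per-lineage exclusion counts by reason.
#' @export
hs_ho <- function(hits, reads, clusters, annotations, analysed) {
  if (length(unique(analysed$sample)) < 2)
    stop("Hs/Ho is undefined for a single-sample dataset")
  reads <- data.table::as.data.table(reads)
  info <- merge(clusters$membership,
                annotations[, list(cluster_id, lineage)], by = "cluster_id")
  info <- merge(info, reads[, list(read_id = id, sample)], by = "read_id")

  long <- rbind(hits[, list(read_id = read_a, other = read_b)],
                hits[, list(read_id = read_b, other = read_a)])
  long <- merge(long, reads[, list(other = id, other_sample = sample)],
                by = "other")
  long <- merge(long, info, by = "read_id")
  per <- long[, list(Hs = sum(other_sample == sample[1]),
                     Ho_raw = sum(other_sample != sample[1])),
              by = list(read_id, sample, lineage)]
  # clustered annotated reads with no counted edges at all keep Hs=Ho=0
  missing <- info[!per, on = "read_id"]
  if (nrow(missing))
    per <- rbind(per, missing[, list(read_id, sample, lineage,
                                     Hs = 0L, Ho_raw = 0L)])

  totals <- setNames(analysed$n_reads, analysed$sample)
  n_all <- sum(totals)
  per[, Ho_norm := Ho_raw * (totals[sample] - 1) / (n_all - totals[sample])]

  excluded <- per[Hs == 0L | Ho_raw == 0L,
                  list(n = .N),
                  by = list(lineage,
                            reason = ifelse(Hs == 0L & Ho_raw == 0L, "no_hits",
                                     ifelse(Hs == 0L, "zero_Hs", "zero_Ho")))]
  records <- per[Hs > 0L & Ho_raw > 0L]
  records[, log_ratio := log10(Hs / Ho_norm)]
  data.table::setorder(records, lineage, read_id)
  out <- records[, list(read_id, sample, lineage, Hs, Ho_raw, Ho_norm,
                        log_ratio)]
  data.table::setattr(out, "excluded", excluded[])
  out[]
}

#' Fixed-bin log10(Hs/Ho) histograms per lineage
#'
#' Bins of width `bin_width` over `range` (defaults 0.1 over \[-3, 3\]);
#' ratios outside the range are clamped into the edge bins. The mode bin
#' (highest count; ties broken toward the smaller center) is reported per
#' lineage.
#'
#' @param records output of [hs_ho()].
#' @param bin_width bin width on the log10 scale.
#' @param range histogram range on the log10 scale.
#' @return list with `histogram` (data.table: `lineage`, `bin_center`,
#'   `count`) and `modes` (data.table: `lineage`, `mode_center`,
#'   `mode_count`, `n`); empty input yields empty tables with attribute
#'   `empty = TRUE` on the histogram.
#' @export
landscape_histograms <- function(records, bin_width = 0.1,
                                 range = c(-3, 3)) {
  edges <- seq(range[1], range[2], by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  if (is.null(records) || nrow(records) == 0) {
    hist <- data.table::data.table(lineage = character(),
                                   bin_center = numeric(), count = integer())
    data.table::setattr(hist, "empty", TRUE)
    return(list(histogram = hist,
                modes = data.table::data.table(lineage = character(),
                                               mode_center = numeric(),
                                               mode_count = integer(),
                                               n = integer())))
  }
  rec <- data.table::copy(records)
  rec[, bin := pmin(pmax(findInterval(log_ratio, edges,
                                      rightmost.closed = TRUE), 1L),
                    length(centers))]
  hist <- rec[, list(count = .N), by = list(lineage, bin)]
  hist[, bin_center := centers[bin]]
  data.table::setorder(hist, lineage, bin_center)
  modes <- hist[, {
    top <- which(count == max(count))
    list(mode_center = bin_center[top[1]], mode_count = count[top[1]],
         n = sum(count))
  }, by = lineage]
  list(histogram = hist[, list(lineage, bin_center, count)],
       modes = modes[])
}
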