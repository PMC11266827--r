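# simgraph: all-vs-all read-similarity graph under the ungapped overlap
# contract (default 90% identity over >= 55 bp), organelle pre-filtering,
# and connected-component clustering of the resulting graph.

# accept either a read_set or a named/unnamed character vector
read_ids_seqs <- function(reads) {
  if (is.data.frame(reads)) {
    list(ids = as.character(reads$id), seqs = as.character(reads$sequence))
  } else {
    ids <- names(reads) %||% paste0("read", seq_along(reads))
    list(ids = ids, seqs = unname(as.character(reads)))
  }
}

#' Smallest seed length guaranteeing candidate completeness
#'
#' Any ungapped overlap of length `L` with at most `floor((1 -
#' min_identity) * L)` mismatches contains an exact match run of at least
#' `ceil((L - m) / (m + 1))` bases (pigeonhole). Minimizing over admissible
#' overlap lengths gives the largest seed k for which every qualifying pair
#' is guaranteed to share an exact k-mer, making seeded candidate generation
#' provably equivalent to a full scan.
#'
#' @param min_identity minimum identity over the overlap.
#' @param min_overlap minimum overlap length (bp).
#' @param max_length maximum read length (bp).
#' @return integer seed length.
#' @export
guaranteed_seed_k <- function(min_identity, min_overlap, max_length = 101L) {
  L <- seq.int(min_overlap, max(min_overlap, max_length))
  m <- floor((1 - min_identity) * L + 1e-9)
  max(1L, min(ceiling((L - m) / (m + 1))))
}

format_hits <- function(df, ids, min_identity, min_overlap) {
  hits <- data.table::data.table(
    read_a = ids[df$a], read_b = ids[df$b],
    overlap = df$overlap, matches = df$matches, identity = df$identity,
    orientation = c("same", "reverse")[df$orientation + 1L],
    offset = df$offset)
  data.table::setattr(hits, "min_identity", min_identity)
  data.table::setattr(hits, "min_overlap", min_overlap)
  hits[]
}

#' Find all similarity hits between reads
#'
#' Returns every unordered read pair admitting an ungapped overlap alignment
#' (either orientation) of length >= `min_overlap` whose identity, computed
#' over the overlap only, is >= `min_identity`; the best-scoring overlap per
#' pair is reported. Candidate pairs are generated by shared exact k-mer
#' seeding on both strands and every seeded offset is verified exactly, so
#' with the default `seed_k` (from [guaranteed_seed_k()]) the result equals
#' a brute-force all-offset scan.
#'
#' @param reads a `read_set` or character vector of sequences.
#' @param min_identity minimum identity over the overlap (default 0.90).
#' @param min_overlap minimum overlap in bp (default 55).
#' @param seed_k exact-seed length; `NULL` (default) uses the completeness
#'   guarantee for the given thresholds and read lengths.
#' @return data.table with columns `read_a`, `read_b`, `overlap`, `matches`,
#'   `identity`, `orientation` (`"same"`/`"reverse"`), `offset`.
#' @export
find_similarity_hits <- function(reads, min_identity = 0.90,
                                 min_overlap = 55L, seed_k = NULL) {
  rs <- read_ids_seqs(reads)
  if (length(rs$seqs) == 0) stop("no reads supplied")
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0, 1]")
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  seed_k <- seed_k %||% guaranteed_seed_k(min_identity, min_overlap,
                                          max(nchar(rs$seqs)))
  df <- cpp_find_hits(rs$seqs, min_identity, as.integer(min_overlap),
                      as.integer(seed_k))
  format_hits(df, rs$ids, min_identity, min_overlap)
}

#' Brute-force overlap scan (reference oracle)
#'
#' Scans every read pair, orientation and offset without any seeding;
#' algorithmically independent of [find_similarity_hits()] and quadratic in
#' both reads and offsets, so only suitable for small inputs.
#'
#' @inheritParams find_similarity_hits
#' @return same shape as [find_similarity_hits()].
#' @export
brute_force_hits <- function(reads, min_identity = 0.90, min_overlap = 55L) {
  rs <- read_ids_seqs(reads)
  df <- cpp_brute_hits(rs$seqs, min_identity, as.integer(min_overlap))
  format_hits(df, rs$ids, min_identity, min_overlap)
}

#' Remove read pairs matching an organelle reference
#'
#' A read pair is discarded when either mate shares at least `min_matches`
#' k-mers (either strand) with the reference; pairing is preserved in the
#' retained set. Mirrors k-mer based contamination pre-filtering of skim
#' data against plastome/mitogenome references.
#'
#' @param reads a `read_set` (needs `pair_index`).
#' @param organelle_reference character vector of reference sequences.
#' @param k k-mer size (default 24); must not exceed the read length.
#' @param min_matches minimum shared k-mers to discard (default 2).
#' @return the retained `read_set`; attribute `discarded_pairs` holds the
#'   number of removed pairs.
#' @export
filter_organelle <- function(reads, organelle_reference, k = 24L,
                             min_matches = 2L) {
  stopifnot(is.data.frame(reads))
  if (length(organelle_reference) == 0 || all(nchar(organelle_reference) == 0))
    stop("organelle reference is empty")
  if (k > min(nchar(reads$sequence))) stop("k exceeds read length")
  counts <- cpp_ref_kmer_counts(reads$sequence, organelle_reference,
                                as.integer(k))
  bad <- counts >= min_matches
  key <- paste(reads$sample, reads$pair_index)
  bad_pairs <- unique(key[bad])
  keep <- !(key %in% bad_pairs)
  out <- reads[keep]
  data.table::setattr(out, "discarded_pairs", length(bad_pairs))
  out
}

#' Cluster reads from the similarity graph
#'
#' Clusters are the connected components of the hit graph (optionally split
#' by modularity-based community detection), ranked by decreasing size;
#' singleton reads are reported separately as unclustered. Equal-sized
#' clusters are ordered by their smallest member id.
#'
#' @param reads a `read_set` or character vector (defines the node set,
#'   including isolated reads).
#' @param hits hit table from [find_similarity_hits()].
#' @param refine split components by Louvain community detection when their
#'   modularity exceeds `modularity_threshold` (default off: pure connected
#'   components).
#' @param modularity_threshold modularity needed to accept a split.
#' @return a `repeat_clusters` object: list with `clusters` (data.table:
#'   `cluster_id`, `n_reads`, `size_fraction`), `membership` (data.table:
#'   `read_id`, `cluster_id`), `unclustered` (ids), `graph` (igraph),
#'   `total_reads`.
#' @export
cluster_reads <- function(reads, hits, refine = FALSE,
                          modularity_threshold = 0.4) {
  rs <- read_ids_seqs(reads)
  g <- igraph::graph_from_data_frame(
    hits[, list(read_a, read_b)], directed = FALSE,
    vertices = data.frame(name = rs$ids))
  comp <- igraph::components(g)
  member <- comp$membership

  if (refine && length(member)) {
    nxt <- max(member) + 1L
    for (cid in which(comp$csize >= 4L)) {
      vs <- which(member == cid)
      sub <- igraph::induced_subgraph(g, vs)
      cl <- igraph::cluster_louvain(sub)
      if (length(unique(igraph::membership(cl))) > 1L &&
          igraph::modularity(cl) > modularity_threshold) {
        member[vs] <- nxt + igraph::membership(cl) - 1L
        nxt <- nxt + max(igraph::membership(cl))
      }
    }
  }

  dt <- data.table::data.table(read_id = rs$ids, comp = member)
  sizes <- dt[, list(n_reads = .N, member_min = min(read_id)), by = comp]
  clustered <- sizes[n_reads >= 2L]
  data.table::setorder(clustered, -n_reads, member_min)
  clustered[, cluster_id := seq_len(.N)]
  dt <- merge(dt, clustered[, list(comp, cluster_id)], by = "comp",
              all.x = TRUE, sort = FALSE)
  membership <- dt[!is.na(cluster_id), list(read_id, cluster_id)]
  data.table::setorder(membership, cluster_id, read_id)

  total <- length(rs$ids)
  clusters <- clustered[, list(cluster_id, n_reads,
                               size_fraction = n_reads / total)]
  data.table::setorder(clusters, cluster_id)
  structure(list(clusters = clusters[], membership = membership[],
                 unclustered = dt[is.na(cluster_id), read_id],
                 graph = g, total_reads = total),
            class = "repeat_clusters")
}

#' @export
print.repeat_clusters <- function(x, ...) {
  cat("Read clustering:", nrow(x$clusters), "clusters over", x$total_reads,
      "reads;", length(x$unclustered), "unclustered\n")
  print(head(x$clusters, 10))
  invisible(x)
}

#' Keep clusters above a size-fraction threshold
#'
#' @param clusters a `repeat_clusters` object or its `clusters` data.table.
#' @param threshold minimum size fraction (exclusive); the default 1e-4
#'   corresponds to the usual "more than 0.01% of analysed reads" top-cluster
#'   rule.
#' @return the filtered clusters table.
#' @export
filter_top_clusters <- function(clusters, threshold = 1e-4) {
  tab <- if (inherits(clusters, "repeat_clusters")) clusters$clusters
         else clusters
  tab[tab$size_fraction > threshold, ]
}

#' Per-cluster, per-sample read counts
#'
#' @param clusters a `repeat_clusters` object.
#' @param reads the `read_set` the clustering was built from.
#' @return data.table `cluster_id`, `sample`, `n`.
#' @export
cluster_sample_counts <- function(clusters, reads) {
  mm <- merge(clusters$membership,
              data.table::as.data.table(reads)[, list(read_id = id, sample)],
              by = "read_id")
  mm[, list(n = .N), by = list(cluster_id, sample)]
}

#' Write / read a hitsort-style TSV
#'
#' Columns `read_a`, `read_b`, `overlap`, `identity`, `orientation` (the
#' edge list of the read-similarity graph).
#'
#' @param hits hit table.
#' @param path file path.
#' @return `path` / the hit table.
#' @export
write_hitsort <- function(hits, path) {
  data.table::fwrite(hits[, list(read_a, read_b, overlap, identity,
                                 orientation)], path, sep = "\t")
  invisible(path)
}

#' @rdname write_hitsort
#' @export
read_hitsort <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' Write cluster membership as TSV (read_id, cluster_id)
#'
#' @param clusters a `repeat_clusters` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cluster_membership <- function(clusters, path) {
  data.table::fwrite(clusters$membership, path, sep = "\t")
  invisible(path)
}
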