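# tandemgraph: characterization of tandem-repeat clusters. Connected
# component index, greedy k-mer consensus with coverage score over a sweep
# of k sizes, and 5S rDNA graph typing by counting intergenic-spacer (IGS)
# "loops" as divergent IGS read sub-clusters joined by the conserved gene.

#' Connected-component index of a cluster subgraph
#'
#' Fraction of the subgraph's nodes in its largest connected component;
#' near 1 for intact tandem clusters.
#'
#' @param graph an igraph subgraph.
#' @return C index in (0, 1].
#' @export
c_index <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph")
  max(igraph::components(graph)$csize) / n
}

#' Induced subgraph of one cluster
#'
#' @param clusters a `repeat_clusters` object.
#' @param id cluster id.
#' @return igraph subgraph over the cluster's member reads.
#' @export
cluster_subgraph <- function(clusters, id) {
  members <- clusters$membership[cluster_id == id, read_id]
  igraph::induced_subgraph(clusters$graph, members)
}

# canonical k-mer counts of a read set, as a hashed environment plus total
canonical_kmer_counts <- function(seqs, k) {
  kms <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  kms <- kms[!grepl("[^ACGT]", kms)]
  if (length(kms) == 0) return(NULL)
  canon <- pmin(kms, revcomp(kms))
  dt <- data.table::data.table(canon = canon)[, list(count = .N), by = canon]
  env <- new.env(hash = TRUE, size = nrow(dt) * 2L)
  for (i in seq_len(nrow(dt))) assign(dt$canon[i], dt$count[i], envir = env)
  list(env = env, total = length(kms), top = dt$canon[which.max(dt$count)])
}

kmer_count <- function(counts, kmer) {
  canon <- if (kmer <= (rc <- revcomp(kmer))) kmer else rc
  get0(canon, envir = counts$env, ifnotfound = 0L)
}

# greedy max-weight circular walk in oriented k-mer space
greedy_cycle <- function(counts, k, max_steps = 20000L) {
  node <- counts$top
  start <- node
  visited <- new.env(hash = TRUE)
  path <- character(max_steps)
  np <- 0L
  repeat {
    np <- np + 1L
    if (np > max_steps) return(NULL)
    path[np] <- node
    assign(if (node <= (rc <- revcomp(node))) node else rc, TRUE,
           envir = visited)
    suff <- substr(node, 2L, k)
    cand <- paste0(suff, DNA_BASES)
    cnt <- vapply(cand, function(x) kmer_count(counts, x), integer(1))
    if (all(cnt == 0L)) return(NULL)          # dead end: no successor
    nxt <- cand[which.max(cnt)]
    if (nxt == start) break                    # cycle closed
    ncanon <- if (nxt <= (rc <- revcomp(nxt))) nxt else rc
    if (!is.null(get0(ncanon, envir = visited))) return(NULL)  # tail loop
    node <- nxt
  }
  path[seq_len(np)]
}

#' k-mer consensus of a tandem cluster with coverage score
#'
#' For each candidate k, counts canonicalized k-mers of the cluster's reads,
#' greedily extracts the highest-weight circular path starting from the most
#' frequent k-mer, and scores it as kmer_coverage = (sum of frequencies of
#' path k-mers) / (sum of all k-mer frequencies). The consensus (one linear
#' monomer of the circular path) and coverage for the coverage-maximizing k
#' are returned; clusters where no k yields a cycle are flagged non-tandem.
#'
#' @param reads cluster member reads (`read_set` or character vector).
#' @param k_candidates candidate k sizes (defaults 11, 15, 19, 23, 27).
#' @return list `consensus`, `consensus_length`, `kmer_coverage`, `k`,
#'   `non_tandem`.
#' @export
kmer_consensus <- function(reads, k_candidates = c(11L, 15L, 19L, 23L, 27L)) {
  seqs <- read_ids_seqs(reads)$seqs
  k_candidates <- k_candidates[k_candidates < min(nchar(seqs))]
  if (length(k_candidates) == 0) stop("reads shorter than every candidate k")
  best <- list(consensus = NA_character_, consensus_length = NA_integer_,
               kmer_coverage = 0, k = NA_integer_, non_tandem = TRUE)
  for (k in k_candidates) {
    counts <- canonical_kmer_counts(seqs, k)
    if (is.null(counts)) next
    path <- greedy_cycle(counts, k)
    if (is.null(path)) next
    canon <- unique(pmin(path, revcomp(path)))
    onpath <- sum(vapply(canon, function(x)
      get0(x, envir = counts$env, ifnotfound = 0L), integer(1)))
    coverage <- onpath / counts$total
    if (coverage > best$kmer_coverage) {
      best <- list(consensus = paste(substr(path, 1L, 1L), collapse = ""),
                   consensus_length = length(path),
                   kmer_coverage = coverage, k = as.integer(k),
                   non_tandem = FALSE)
    }
  }
  best
}

#' Type a 5S rDNA cluster graph by IGS loop counting
#'
#' Reads are split into gene-matching reads (>= `gene_identity` identity to
#' the conserved 5S gene exemplar over >= `gene_overlap` bp) and IGS reads;
#' IGS reads are re-clustered under the standard similarity contract and
#' each sub-cluster holding at least `loop_min_frac` of the cluster's reads
#' counts as one loop (interconnected loops represent IGS spacers, so the
#' number of well-occupied IGS sub-clusters is the ribotype count). The
#' graph type is the loop count clamped to 1..3: type 1 simple circular
#' graph, types 2 and 3 complex graphs with two or three loops.
#'
#' @param reads member reads of a 5S-annotated cluster.
#' @param gene conserved 5S gene exemplar sequence.
#' @param min_identity,min_overlap IGS re-clustering contract (defaults
#'   0.90 / 55).
#' @param gene_identity,gene_overlap gene-match thresholds (defaults 0.80 /
#'   40).
#' @param loop_min_frac minimum fraction of cluster reads for a sub-cluster
#'   to count as a loop (default 0.05).
#' @return list `loop_count`, `graph_type`, `n_gene_reads`, `n_igs_reads`.
#' @export
classify_5s_graph <- function(reads, gene, min_identity = 0.90,
                              min_overlap = 55L, gene_identity = 0.80,
                              gene_overlap = 40L, loop_min_frac = 0.05) {
  rs <- read_ids_seqs(reads)
  n_total <- length(rs$seqs)
  is_gene <- cpp_matches_ref(rs$seqs, gene, gene_identity,
                             as.integer(gene_overlap))
  if (!any(is_gene)) stop("classification error: no gene-matching reads")
  igs <- rs$seqs[!is_gene]
  names(igs) <- rs$ids[!is_gene]
  loop_count <- 0L
  if (length(igs) >= 2) {
    hits <- find_similarity_hits(igs, min_identity, min_overlap)
    cl <- cluster_reads(igs, hits)
    loop_count <- sum(cl$clusters$n_reads >= loop_min_frac * n_total)
  }
  list(loop_count = loop_count,
       graph_type = min(max(loop_count, 1L), 3L),
       n_gene_reads = sum(is_gene), n_igs_reads = length(igs))
}

#' Tandem-cluster profile (consensus, coverage, C index, graph type)
#'
#' Convenience wrapper assembling the per-cluster row of a tandem-repeat
#' report: read count, genome proportion, k-mer consensus and coverage,
#' connected-component index, and (when a 5S gene exemplar is supplied) the
#' IGS loop count and graph type.
#'
#' @param reads cluster member reads.
#' @param subgraph optional igraph cluster subgraph for the C index; when
#'   `NULL` it is rebuilt from the reads at the standard contract.
#' @param gene optional conserved 5S gene exemplar.
#' @param genome_proportion optional genome proportion of the cluster.
#' @param ... passed to [classify_5s_graph()].
#' @return one-row data.table.
#' @export
tandem_profile <- function(reads, subgraph = NULL, gene = NULL,
                           genome_proportion = NA_real_, ...) {
  rs <- read_ids_seqs(reads)
  if (is.null(subgraph)) {
    hits <- find_similarity_hits(reads)
    subgraph <- igraph::graph_from_data_frame(
      hits[, list(read_a, read_b)], directed = FALSE,
      vertices = data.frame(name = rs$ids))
  }
  cons <- kmer_consensus(reads)
  typed <- if (!is.null(gene)) classify_5s_graph(reads, gene, ...)
           else list(loop_count = NA_integer_, graph_type = NA_integer_)
  data.table::data.table(
    n_reads = length(rs$seqs), genome_proportion = genome_proportion,
    consensus_length = cons$consensus_length,
    kmer_coverage = cons$kmer_coverage, c_index = c_index(subgraph),
    loop_count = typed$loop_count, graph_type = typed$graph_type,
    non_tandem = cons$non_tandem, consensus = cons$consensus)
}
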