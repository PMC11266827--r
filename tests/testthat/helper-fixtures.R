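# shared in-code fixtures for the test suite

# a tiny read_set built directly from sequences (ids SAMP_xxxxx/m)
make_read_set <- function(seqs, sample_code = "TEST", mates = NULL) {
  n <- length(seqs)
  mates <- mates %||% rep(1:2, length.out = n)
  pair <- cumsum(mates == 1L)
  rs <- data.table::data.table(
    id = paste0(sample_code, "_", formatC(pair, width = 7, flag = "0"),
                "/", mates),
    sequence = seqs, sample = sample_code, mate = mates,
    pair_index = pair, origin = NA_character_)
  data.table::setattr(rs, "class", c("read_set", class(data.table::data.table())))
  rs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reads tiling a circular monomer at every offset (error-free, forward)
tile_circular <- function(monomer, read_length = 101L) {
  circ <- paste0(monomer, monomer)
  substring(circ, seq_len(nchar(monomer)),
            seq_len(nchar(monomer)) + read_length - 1L)
}

# minimal repeat_clusters object for arithmetic tests
fake_clusters <- function(membership, total_reads) {
  sizes <- membership[, list(n_reads = .N), by = cluster_id]
  data.table::setorder(sizes, cluster_id)
  structure(list(
    clusters = sizes[, list(cluster_id, n_reads,
                            size_fraction = n_reads / total_reads)],
    membership = membership, unclustered = character(),
    graph = NULL, total_reads = total_reads),
    class = "repeat_clusters")
}

# smallest circular-alignment distance between two monomers (either strand)
circular_mismatch <- function(consensus, truth) {
  stopifnot(nchar(consensus) == nchar(truth))
  n <- nchar(truth)
  best <- n
  for (cand in c(consensus, skimrep::revcomp(consensus))) {
    circ <- paste0(cand, cand)
    tv <- strsplit(truth, "")[[1]]
    for (r in seq_len(n)) {
      rot <- strsplit(substr(circ, r, r + n - 1L), "")[[1]]
      best <- min(best, sum(rot != tv))
      if (best == 0) return(0L)
    }
  }
  best
}
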