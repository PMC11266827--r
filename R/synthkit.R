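# synthkit: seeded generation of multi-sample genome-skimming datasets with
# planted repeat families, polyploid subgenome structure and 5S ribotype
# arrays. Every simulated object carries exact ground truth so downstream
# estimates can be scored against planted values.

#' Describe a repeat family to plant in a simulated genome
#'
#' @param name family label (e.g. `"Retand"`, `"satCEN"`).
#' @param lineage one of `"LTR-Gypsy"`, `"LTR-Copia"`, `"DNA-transposon"`,
#'   `"satellite"`, `"rDNA-5S"`, `"other"`.
#' @param monomer_length monomer/element length in bp (>= 20).
#' @param copies_per_monoploid number of planted copies (>= 0).
#' @param divergence expected per-base substitution fraction of each copy
#'   from the family consensus, in `[0, 0.25]`.
#' @param tandem logical; tandem families (satellites) are planted as one
#'   head-to-tail array, mobile elements as dispersed copies.
#' @param consensus optional explicit consensus sequence; when `NULL` a
#'   random consensus of `monomer_length` bp is drawn at simulation time.
#' @return a `repeat_family_spec` list.
#' @export
repeat_family <- function(name, lineage, monomer_length, copies_per_monoploid,
                          divergence = 0, tandem = FALSE, consensus = NULL) {
  lineage <- match.arg(lineage, c("LTR-Gypsy", "LTR-Copia", "DNA-transposon",
                                  "satellite", "rDNA-5S", "other"))
  if (monomer_length < 20) stop("monomer_length must be >= 20")
  if (divergence < 0 || divergence > 0.25) stop("divergence must be in [0, 0.25]")
  if (copies_per_monoploid < 0) stop("copies_per_monoploid must be >= 0")
  if (!is.null(consensus) && nchar(consensus) != monomer_length)
    stop("consensus length must equal monomer_length")
  structure(list(name = name, lineage = lineage,
                 monomer_length = as.integer(monomer_length),
                 copies_per_monoploid = as.integer(copies_per_monoploid),
                 divergence = divergence, tandem = isTRUE(tandem),
                 consensus = consensus),
            class = "repeat_family_spec")
}

#' Describe a 5S rDNA array (conserved gene + ribotype-specific spacers)
#'
#' A 5S locus is modelled as a tandem array of units, each a highly conserved
#' gene followed by an intergenic spacer (IGS); distinct IGS consensus
#' sequences ("ribotypes") mark distinct loci/subgenomes.
#'
#' @param gene conserved 5S gene sequence (>= 60 bp).
#' @param igs_variants character vector of 1-4 spacer consensus sequences,
#'   one per ribotype.
#' @param array_copies units per ribotype array.
#' @param within_divergence per-base substitution rate of each planted unit
#'   from its ribotype consensus; must stay below the divergence between
#'   ribotype spacers.
#' @return a `five_s_spec` list.
#' @export
five_s_unit <- function(gene, igs_variants, array_copies = 40,
                        within_divergence = 0.005) {
  if (nchar(gene) < 60) stop("gene must be >= 60 bp")
  nv <- length(igs_variants)
  if (nv < 1 || nv > 4) stop("between 1 and 4 IGS variants required")
  if (array_copies < 1) stop("array_copies must be >= 1")
  structure(list(gene = gene, igs_variants = as.character(igs_variants),
                 array_copies = as.integer(array_copies),
                 within_divergence = within_divergence),
            class = "five_s_spec")
}

#' Random 5S specification with divergent ribotypes
#'
#' Draws a conserved gene and `n_ribotypes` independent random spacers
#' (pairwise identity ~25%, far below any hit threshold), emulating the
#' conserved-gene / variable-IGS architecture of 5S arrays.
#'
#' @param n_ribotypes number of ribotypes (1-4).
#' @param gene_length,igs_length unit part lengths in bp.
#' @param array_copies units per ribotype array.
#' @param within_divergence see [five_s_unit()].
#' @param gene optional shared gene sequence (so several samples can carry
#'   the same conserved gene).
#' @return a `five_s_spec`.
#' @export
random_five_s <- function(n_ribotypes, gene_length = 120, igs_length = 250,
                          array_copies = 40, within_divergence = 0.005,
                          gene = NULL) {
  gene <- gene %||% random_dna(gene_length)
  igs <- vapply(seq_len(n_ribotypes), function(i) random_dna(igs_length), "")
  five_s_unit(gene, igs, array_copies, within_divergence)
}

#' Blueprint of one monoploid genome
#'
#' @param background_length bp of non-repetitive random background.
#' @param families list of [repeat_family()] specs.
#' @param five_s optional [five_s_unit()] spec.
#' @return a `genome_blueprint` list.
#' @export
genome_blueprint <- function(background_length, families = list(),
                             five_s = NULL) {
  stopifnot(background_length >= 0)
  structure(list(background_length = as.integer(background_length),
                 families = families, five_s = five_s),
            class = "genome_blueprint")
}

#' Multi-subgenome sample specification
#'
#' @param sample_code exactly 4 characters; becomes the read-header prefix
#'   from which sample membership is recovered downstream.
#' @param subgenomes list of [genome_blueprint()]s, one per monoploid
#'   complement (repeat an entry for autopolyploid multiplicity).
#' @param nx ploidy; must equal `length(subgenomes)`.
#' @param seed integer master seed for this sample.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(sample_code, subgenomes, nx = length(subgenomes),
                        seed = 1L) {
  if (nchar(sample_code) != 4) stop("sample_code must be exactly 4 characters")
  if (length(subgenomes) < 1) stop("at least one subgenome required")
  if (nx != length(subgenomes))
    stop("nx must equal the number of subgenome blueprints")
  structure(list(sample_code = sample_code, subgenomes = subgenomes,
                 nx = as.integer(nx), seed = as.integer(seed)),
            class = "genome_spec")
}

# build the mutated copies of one family; returns list of insert strings
build_family_inserts <- function(fam) {
  cons <- fam$consensus %||% random_dna(fam$monomer_length)
  chars <- strsplit(cons, "", fixed = TRUE)[[1]]
  copies <- replicate(fam$copies_per_monoploid,
                      paste(mutate_chars(chars, fam$divergence), collapse = ""),
                      simplify = FALSE)
  if (fam$tandem && length(copies) > 0) {
    list(consensus = cons, inserts = list(paste(unlist(copies), collapse = "")),
         copies = fam$copies_per_monoploid)
  } else {
    list(consensus = cons, inserts = copies, copies = fam$copies_per_monoploid)
  }
}

#' Simulate one monoploid genome sequence with planted truth
#'
#' The background is uniform random DNA; each dispersed family's copies are
#' inserted at uniformly random non-overlapping positions with independent
#' per-base substitutions at the family's divergence rate; tandem families
#' become one head-to-tail array; a 5S spec becomes one gene+IGS array per
#' ribotype. Substitution-only mutation keeps planted base counts exact.
#'
#' @param blueprint a [genome_blueprint()].
#' @param seed integer seed; identical blueprint + seed give byte-identical
#'   output.
#' @return list with `sequence`, `features` (data.table: start, end, family,
#'   lineage; 1-based inclusive), `truth` (data.table: family, lineage,
#'   bases, copies), `consensus` (named list of family consensus sequences),
#'   `ribotypes` (IGS variant sequences planted), `length`.
#' @export
simulate_monoploid <- function(blueprint, seed = 1L) {
  stopifnot(inherits(blueprint, "genome_blueprint"))
  with_seed(seed, {
    B <- blueprint$background_length
    background <- if (B > 0) random_dna(B) else ""

    inserts <- character()
    ins_family <- character()
    ins_lineage <- character()
    truth_rows <- list()
    consensus <- list()
    ribotypes <- character()

    for (fam in blueprint$families) {
      built <- build_family_inserts(fam)
      consensus[[fam$name]] <- built$consensus
      if (length(built$inserts)) {
        inserts <- c(inserts, unlist(built$inserts))
        ins_family <- c(ins_family, rep(fam$name, length(built$inserts)))
        ins_lineage <- c(ins_lineage, rep(fam$lineage, length(built$inserts)))
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.table::data.table(
        family = fam$name, lineage = fam$lineage,
        bases = sum(nchar(unlist(built$inserts))), copies = built$copies)
    }

    fs <- blueprint$five_s
    if (!is.null(fs)) {
      unit_bases <- 0L
      for (v in fs$igs_variants) {
        unit <- paste0(fs$gene, v)
        chars <- strsplit(unit, "", fixed = TRUE)[[1]]
        arr <- paste(replicate(fs$array_copies,
                               paste(mutate_chars(chars, fs$within_divergence),
                                     collapse = "")),
                     collapse = "")
        inserts <- c(inserts, arr)
        ins_family <- c(ins_family, "5S")
        ins_lineage <- c(ins_lineage, "rDNA-5S")
        unit_bases <- unit_bases + nchar(arr)
        ribotypes <- c(ribotypes, v)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.table::data.table(
        family = "5S", lineage = "rDNA-5S", bases = unit_bases,
        copies = fs$array_copies * length(fs$igs_variants))
      consensus[["5S_gene"]] <- fs$gene
    }

    rep_bases <- sum(nchar(inserts))
    if (rep_bases > B)
      stop("sizing error: planted repeat length (", rep_bases,
           " bp) exceeds background capacity (", B, " bp)")

    # insertion points in the gaps between background bases: trivially
    # non-overlapping, uniform over the background
    if (length(inserts)) {
      gaps <- sort(sample.int(B + 1L, length(inserts), replace = TRUE)) - 1L
      ord <- seq_along(inserts)  # keep draw order stable under sort by gap
      o <- order(gaps, ord)
      gaps <- gaps[o]; inserts <- inserts[o]
      ins_family <- ins_family[o]; ins_lineage <- ins_lineage[o]

      pieces <- character(2L * length(inserts) + 1L)
      feats_start <- integer(length(inserts))
      feats_end <- integer(length(inserts))
      prev <- 0L; at <- 0L
      for (i in seq_along(inserts)) {
        pieces[2L * i - 1L] <- substr(background, prev + 1L, gaps[i])
        at <- at + (gaps[i] - prev)
        feats_start[i] <- at + 1L
        at <- at + nchar(inserts[i])
        feats_end[i] <- at
        pieces[2L * i] <- inserts[i]
        prev <- gaps[i]
      }
      pieces[2L * length(inserts) + 1L] <- substr(background, prev + 1L, B)
      sequence <- paste(pieces, collapse = "")
      features <- data.table::data.table(start = feats_start, end = feats_end,
                                         family = ins_family,
                                         lineage = ins_lineage)
    } else {
      sequence <- background
      features <- data.table::data.table(start = integer(), end = integer(),
                                         family = character(),
                                         lineage = character())
    }

    truth <- if (length(truth_rows)) data.table::rbindlist(truth_rows)
             else data.table::data.table(family = character(),
                                         lineage = character(),
                                         bases = integer(), copies = integer())

    list(sequence = sequence, features = features, truth = truth,
         consensus = consensus, ribotypes = ribotypes,
         length = nchar(sequence))
  })
}

#' Combine monoploid sequences into a holoploid genome
#'
#' The holoploid genome is the multiset union of its subgenome sequences;
#' planted truth proportions are recomputed over the holoploid length.
#'
#' @param monoploids list of [simulate_monoploid()] results.
#' @return list with `sequences`, `features` (per sequence), `truth`
#'   (aggregated, with `proportion` over holoploid length), `ribotype_count`,
#'   `ribotypes`, `length`.
#' @export
make_polyploid <- function(monoploids) {
  if (length(monoploids) < 1) stop("empty subgenome list")
  total <- sum(vapply(monoploids, `[[`, integer(1), "length"))
  truth <- data.table::rbindlist(lapply(monoploids, `[[`, "truth"))
  if (nrow(truth)) {
    truth <- truth[, .(bases = sum(bases), copies = sum(copies)),
                   by = .(family, lineage)]
    truth[, proportion := bases / total]
  } else {
    truth[, proportion := numeric()]
  }
  ribos <- unique(unlist(lapply(monoploids, `[[`, "ribotypes")))
  cons <- unlist(lapply(monoploids, `[[`, "consensus"))
  list(sequences = lapply(monoploids, `[[`, "sequence"),
       consensus = cons,
       features = lapply(monoploids, `[[`, "features"),
       truth = truth,
       ribotype_count = length(ribos), ribotypes = ribos,
       length = total)
}

#' Simulate the holoploid genome of a sample specification
#'
#' Each subgenome gets an independent seed derived from the sample seed, so
#' repeated blueprint entries (autopolyploidy) yield independent copy
#' realizations of the same families.
#'
#' @param spec a [genome_spec()].
#' @return [make_polyploid()] result plus `sample_code` and `nx`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  monos <- lapply(seq_along(spec$subgenomes), function(i)
    simulate_monoploid(spec$subgenomes[[i]],
                       seed = derive_seed(spec$seed, paste0("subgenome", i))))
  g <- make_polyploid(monos)
  g$sample_code <- spec$sample_code
  g$nx <- spec$nx
  g
}

# feature lookup by position midpoint; returns family label or "background"
origin_of <- function(features, mids) {
  if (is.null(features) || nrow(features) == 0L)
    return(rep("background", length(mids)))
  idx <- findInterval(mids, features$start)
  out <- rep("background", length(mids))
  hit <- idx > 0L
  hit[hit] <- mids[hit] <= features$end[idx[hit]]
  out[hit] <- features$family[idx[hit]]
  out
}

#' Draw paired-end skim reads from a (holoploid) genome
#'
#' Fragments are placed uniformly; the second mate is the reverse complement
#' of the fragment end; per-base substitution errors are applied at
#' `error_rate`. Headers are `<sample_code>_<pair index>/<mate>` so the
#' 4-character sample code is always recoverable from a read id. The number
#' of pairs is `floor(coverage * genome_length / (2 * read_length))`.
#'
#' @param genome [simulate_genome()]/[make_polyploid()] result, or a
#'   character vector of sequences.
#' @param coverage haploid genome coverage in `(0, 0.5]` (genome-skimming
#'   depth).
#' @param read_length read length in bp (default 101).
#' @param insert_range inclusive fragment-size range; minimum must be >=
#'   `read_length` (mates may overlap when insert < 2 * read_length).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @param sample_code 4-character code; defaults to the genome's own code.
#' @return a `read_set` data.table with columns `id`, `sequence`, `sample`,
#'   `mate`, `pair_index`, `origin` (planted family of the mate midpoint, or
#'   `"background"`).
#' @export
skim_reads <- function(genome, coverage, read_length = 101L,
                       insert_range = c(123L, 329L), error_rate = 0.005,
                       seed = 1L, sample_code = NULL) {
  if (is.character(genome)) {
    genome <- list(sequences = as.list(genome),
                   features = vector("list", length(genome)),
                   length = sum(nchar(genome)))
  }
  sample_code <- sample_code %||% genome$sample_code
  if (is.null(sample_code) || nchar(sample_code) != 4)
    stop("a 4-character sample_code is required")
  if (coverage <= 0 || coverage > 0.5)
    stop("coverage must be in (0, 0.5]")
  if (min(insert_range) < read_length)
    stop("minimum insert must be >= read_length")
  lens <- vapply(genome$sequences, nchar, integer(1))
  if (min(lens) < max(insert_range))
    stop("genome sequence shorter than maximum insert size")

  G <- sum(lens)
  n_pairs <- floor(coverage * G / (2 * read_length))
  if (n_pairs < 1) stop("coverage too low: zero read pairs")

  with_seed(seed, {
    seq_idx <- sample.int(length(lens), n_pairs, replace = TRUE,
                          prob = lens / G)
    insert <- insert_range[1] + floor(runif(n_pairs) *
                                      (insert_range[2] - insert_range[1] + 1))
    start <- floor(runif(n_pairs) * (lens[seq_idx] - insert + 1)) + 1

    m1 <- character(n_pairs); m2 <- character(n_pairs)
    o1 <- character(n_pairs); o2 <- character(n_pairs)
    for (s in unique(seq_idx)) {
      w <- which(seq_idx == s)
      sq <- genome$sequences[[s]]
      m1[w] <- substring(sq, start[w], start[w] + read_length - 1)
      e2 <- start[w] + insert[w] - 1
      m2[w] <- substring(sq, e2 - read_length + 1, e2)
      fe <- genome$features[[s]]
      o1[w] <- origin_of(fe, start[w] + (read_length - 1) / 2)
      o2[w] <- origin_of(fe, e2 - (read_length - 1) / 2)
    }
    m2 <- revcomp(m2)

    seqs <- character(2L * n_pairs)
    seqs[c(TRUE, FALSE)] <- m1
    seqs[c(FALSE, TRUE)] <- m2
    if (error_rate > 0) {
      nerr <- rbinom(length(seqs), read_length, error_rate)
      for (i in which(nerr > 0L)) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(read_length, nerr[i])
        shift <- sample.int(3L, nerr[i], replace = TRUE)
        cur <- match(chars[pos], DNA_BASES)
        ok <- !is.na(cur)
        chars[pos[ok]] <- DNA_BASES[(cur[ok] - 1L + shift[ok]) %% 4L + 1L]
        seqs[i] <- paste(chars, collapse = "")
      }
    }

    origin <- character(2L * n_pairs)
    origin[c(TRUE, FALSE)] <- o1
    origin[c(FALSE, TRUE)] <- o2
    pair_index <- rep(seq_len(n_pairs), each = 2L)
    mate <- rep(1:2, n_pairs)
    reads <- data.table::data.table(
      id = paste0(sample_code, "_", formatC(pair_index, width = 7, flag = "0"),
                  "/", mate),
      sequence = seqs, sample = sample_code, mate = mate,
      pair_index = pair_index, origin = origin)
    data.table::setattr(reads, "class",
                        c("read_set", class(data.table::data.table())))
    reads
  })
}

#' Write reads as (interleaved) FASTA
#'
#' Mates alternate `/1`, `/2` in pair order, matching the interleaved-pair
#' input convention of similarity-graph read clustering.
#'
#' @param reads a `read_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  lines <- character(2L * nrow(reads))
  lines[c(TRUE, FALSE)] <- paste0(">", reads$id)
  lines[c(FALSE, TRUE)] <- reads$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Write reads as FASTQ (uniform Sanger quality "I")
#'
#' @inheritParams write_reads_fasta
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
  lines[c(FALSE, TRUE, FALSE, FALSE)] <- reads$sequence
  lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  lines[c(FALSE, FALSE, FALSE, TRUE)] <- strrep("I", nchar(reads$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Write a planted-truth table as TSV
#'
#' @param truth truth data.table from [simulate_genome()] etc.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' Evolve a repeat consensus along a phylogeny
#'
#' Starting from one ancestral consensus, substitutions accumulate
#' independently along every branch at `rate` substitutions per base per
#' unit branch length, yielding one diverged consensus per tip. Planting
#' the tip consensus of each sample turns known tree structure into
#' cross-sample repeat divergence.
#'
#' @param consensus ancestral consensus sequence.
#' @param tree a `phylo` tree whose tip labels name the samples.
#' @param rate substitutions per base per unit branch length.
#' @return named character vector of tip consensus sequences.
#' @export
evolve_consensus <- function(consensus, tree, rate = 1) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- strsplit(consensus, "", fixed = TRUE)[[1]]
  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    pa <- edges$edge[e, 1]; ch <- edges$edge[e, 2]
    bl <- edges$edge.length[e]
    seqs[[ch]] <- mutate_chars(seqs[[pa]], min(1, rate * bl))
  }
  out <- vapply(seq_len(n_tip), function(t) paste(seqs[[t]], collapse = ""), "")
  names(out) <- tree$tip.label
  out
}
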