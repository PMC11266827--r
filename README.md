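# skimrep

Repeatome quantification and phylogenomics from genome-skimming reads.

High-copy repetitive DNA — LTR retrotransposons (Gypsy lineages such as
Retand, Tekay, Ogre; Copia lineages such as Angela, SIRE), DNA transposons,
satellites and tandem 5S rDNA — drives most genome-size variation in
plants. At skimming depth (0.01–0.5x) only high-copy sequence is sampled
repeatedly, so similarity among raw reads estimates repeat composition
directly: reads are nodes, ungapped overlaps of >= 55 bp at >= 90% identity
are edges, and connected components of this graph are repeat clusters whose
read counts are genome proportions. `skimrep` implements this analysis
chain for multi-sample, multi-ploidy designs (its worked data are the
*Brachypodium* model grasses):

* **synthkit** — seeded simulation of multi-sample skim datasets with
  planted repeat families, polyploid subgenomes, 5S ribotype arrays and
  exact ground truth (`repeat_family()`, `genome_spec()`,
  `simulate_genome()`, `skim_reads()`, `evolve_consensus()`).
* **simgraph** — organelle k-mer pre-filter, the seeded-and-verified
  overlap hit finder with a brute-force oracle (`find_similarity_hits()`,
  `brute_force_hits()`), clustering and top-cluster filtering.
* **repquant** — cluster annotation by k-mer voting against a labelled
  library, genome proportions and Mbp/1Cx amounts, genome-size arithmetic
  (`monoploid_size()`, `pg_to_mbp()`, `fold_ratio()`).
* **tandemgraph** — tandem-cluster profiles: connected-component index,
  k-mer consensus with coverage score, and 5S graph typing by IGS loop
  counting (`kmer_consensus()`, `classify_5s_graph()`).
* **divland** — per-read intraspecific/interspecific hit ratios
  (`hs_ho()`) and their log10 landscape histograms.
* **repnet** — per-cluster observed/expected inter-sample edge matrices,
  inverse-similarity distances, deterministic neighbor joining and the
  consensus split network with a NEXUS writer (`repeat_network()`).
* **repstats** — repeat-abundance vs genome-size statistics: Pearson R²,
  pairwise genome-size-difference contributions, Kruskal–Wallis tests.
* **workbench** — FASTA/FASTQ I/O, interleaving, length filter, YAML
  config and the `run_pipeline()` driver with per-stage count logging.

## Worked example

Genome-size arithmetic on the bundled 44-accession *Brachypodium*
compilation (2C in pg, ploidy nx):

```r
library(skimrep)
tab <- read_genome_size_table(system.file(
  "extdata", "brachypodium_genome_sizes.tsv", package = "skimrep"))
monoploid_size(3.774, 4)   # [1] 0.944  pg, 1Cx of the 4x B. mexicanum
pg_to_mbp(3.774)           # [1] 3690   holoploid Mbp (978 Mbp/pg, floor)
tab[tab$sample == "Bmex347", c("holoploid_mbp", "monoploid_mbp")]
#    holoploid_mbp monoploid_mbp
# 8:          3690           922
fold_ratio(3690, 551)      # [1] 6.7    largest vs smallest holoploid genome
fold_ratio(67.97, 20.77)   # [1] 3.3    repeatome coverage extremes (% 1Cx)
```

An end-to-end simulated run (three diploid-like samples sharing three
repeat families, one 5S locus each):

```r
shared <- with_seed(7, replicate(3, random_dna(1200)))
gene   <- with_seed(8, random_dna(120))
specs  <- lapply(1:3, function(i) {
  fams <- lapply(1:3, function(j)
    repeat_family(paste0("fam", j),
                  c("LTR-Gypsy", "LTR-Copia", "satellite")[j],
                  1200, 15, divergence = 0.02, consensus = shared[j],
                  tandem = j == 3))
  genome_spec(paste0("S", i, "AA"),
              list(genome_blueprint(80000, fams,
                   five_s = with_seed(20 + i,
                     random_five_s(1, gene = gene, array_copies = 20)))),
              seed = 500 + i)
})
lib <- data.frame(sequence = c(shared, gene),
                  lineage = c("Retand", "SIRE", "satellite", "rDNA-5S"))
gs  <- data.frame(sample = c("S1AA", "S2AA", "S3AA"),
                  two_C_pg = 0.2, nx = 2L)
res <- run_pipeline(pipeline_config(specs = specs, coverage = 0.25,
                                    library = lib, five_s_gene = gene,
                                    genome_sizes = gs, seed = 77))
#> [reads] 1050 reads from 3 samples
#> [preprocess] 1050 reads analysed
#> [hits] 2653 similarity hits
#> [clusters] 80 clusters, 80 above size threshold
#> [annotate] 80 clusters annotated
#> [tandem] 2 tandem clusters profiled
#> [hsho] 441 Hs/Ho records
#> [network] 5 trees, 75 clusters excluded
head(res$abundance)
#>    sample      lineage n_reads proportion amount_mbp
#> 1:   S1AA  All repeats     214 0.61142857  59.308571
#> 2:   S1AA       Retand      58 0.16571429  16.074286
#> 3:   S1AA         SIRE      61 0.17428571  16.905714
#> 4:   S1AA Unclassified      47 0.13428571  13.025714
#> 5:   S1AA      rDNA-5S      12 0.03428571   3.325714
#> 6:   S1AA    satellite      36 0.10285714   9.977143
```

Each sample plants 15 copies of three 1.2 kb families plus a small 5S
array in 80 kb of background. The three planted lineages and the 5S
cluster come back annotated with their library labels; the `Unclassified`
share at this toy scale is mostly two-read clusters formed by overlapping
mates of background fragments, and the tiny background clusters are
excluded from the network stage by the complete-matrix rule, leaving the
well-populated family clusters as trees. Calibrated proportion recovery
(estimates within 3 binomial SD of planted truth at 10 Mbp genome scale)
is exercised by `scenario_planted_proportions()`.

`res$abundance` holds per-sample, per-lineage read counts and genome
proportions (an `"All repeats"` row sums them), `res$tandem_profiles` the
consensus length / k-mer coverage / C index / 5S graph type of tandem
clusters, `res$hs_ho` the per-read Hs/Ho records, and `res$network` the
per-cluster NJ trees with their consensus split network.

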