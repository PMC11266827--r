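---
title: "Repeatome analysis from genome-skimming reads: models and methods"
author: "skimrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeatome analysis from genome-skimming reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-copy repetitive DNA (the *repeatome*: LTR retrotransposons, DNA
transposons, satellites, tandem rDNA) dominates genome-size variation in
plants. At genome-skimming depth — 0.01–0.5x of the haploid genome — only
high-copy sequence is sampled repeatedly, so all-vs-all similarity among
raw reads is itself an estimator of repeat composition: reads from a repeat
family overlap each other in proportion to the family's genomic abundance.
`skimrep` implements this analysis chain for multi-sample, multi-ploidy
designs such as the *Brachypodium* model-grass system: read clustering and
per-lineage quantification, tandem/5S rDNA cluster characterization,
cross-sample sequence-diversification statistics, and a repeat-based
phylogenomic network, together with a fully seeded synthetic-data generator
that plants ground truth for every stage.

## The similarity contract

Two reads are connected by a *hit* when some ungapped overlap alignment
(either orientation) spans at least `min_overlap` bases with
`matches / overlap >= min_identity`. Defaults are 90% identity over 55 bp,
the standard settings of graph-based read clustering for 2x101 bp skim
data. Identity is computed over the overlap only; the best-scoring overlap
per read pair is reported (score = matches − mismatches, ties broken by
longer overlap, then orientation, then offset, so output is deterministic).

Candidate pairs are found by shared exact k-mer seeding on both strands and
each seeded offset is verified exactly. The seed length defaults to the
pigeonhole bound: an overlap of length $L$ with at most
$\lfloor(1-\mathrm{id})L\rfloor$ mismatches must contain an exact run of at
least $\lceil (L-m)/(m+1) \rceil$ bases, and minimizing over admissible $L$
(55–101 bp at 90%) gives $k = 8$. Every qualifying pair therefore shares a
seed, which makes the seeded finder provably equivalent to a brute-force
all-offset scan — the package ships that scan (`brute_force_hits()`) as an
independent oracle and the test suite asserts exact agreement. A larger
seed (e.g. the common default 13) would be faster but can miss borderline
overlaps whose mismatches are evenly spaced; we preferred the provable
contract since the verification step dominates runtime anyway.

The overlap model is ungapped. The thresholds are stated as identity and
overlap only, and an ungapped model keeps the oracle exact; at the 0.5%
substitution-only error rate of the simulator this loses nothing, and on
real Illumina data indel errors are rare enough that the 10% mismatch
budget absorbs them.

## Clustering and quantification

Clusters are connected components of the hit graph, ranked by size
(ties by smallest member id); singletons are reported as unclustered.
Modularity-based splitting (Louvain) is available behind
`refine = TRUE` but off by default: components are the defensible minimum,
and on planted-truth simulations they recover family structure directly.
Both mates enter the graph as independent nodes; pairing is metadata only.
Clusters holding more than 0.01% of the analysed reads (`size_threshold =
1e-4`) form the "top cluster" set used downstream.

Organelle contamination is removed before clustering by a k-mer filter:
a read pair is dropped when either mate shares at least 2 exact 24-mers
(either strand) with the organelle reference. With random 101-bp reads the
per-k-mer collision probability is $4^{-24}$, so false discards are
negligible while true plastome reads share dozens of k-mers.

Annotation votes each clustered read for the library lineage sharing the
most 13-mers (both strands); the cluster takes the plurality lineage when
the winning fraction reaches `min_vote = 0.5`, else `Unclassified`.

Genome-size arithmetic follows the conventions of plant genome-size
tables: 1Cx = 2C/nx rounded half-up to 3 decimals (the monoploid
complement of the unreplicated somatic nucleus), pg→Mbp at 978 Mbp/pg with
truncation, and monoploid Mbp = floor(holoploid Mbp / nx). Truncation at
each step (rather than rounding once at the end) is what reproduces the
printed worked values in published tables, e.g. 3.774 pg → 3690 Mbp →
922 Mbp at 4x, and 0.564 pg → 551 Mbp → 275 Mbp at 2x. Abundance is
proportion × monoploid Mbp, with the proportion denominator being the
reads that entered clustering after filters.

## Tandem and 5S rDNA cluster characterization

Tandem clusters are profiled by three statistics:

* **C index** — fraction of the cluster subgraph's nodes in its largest
  connected component; near 1 for intact tandem clusters. Because our
  clusters *are* connected components, the C index of an unmodified
  cluster subgraph is 1 by construction; the function applies to any
  subgraph (e.g. rebuilt under stricter thresholds), and the simulation
  tests use the > 0.95 region observed for real tandem clusters as a
  plausibility band.
* **k-mer consensus and coverage** — for each k in {11, 15, 19, 23, 27},
  canonicalized k-mers of the cluster's reads are counted, a greedy
  highest-weight circular walk is extracted from the most frequent k-mer,
  and coverage = (sum of path k-mer frequencies) / (sum of all k-mer
  frequencies). The k maximizing coverage wins; a cluster with no circular
  walk at any k is flagged non-tandem. This is a deliberately simple
  stand-in for full path-optimization consensus callers: the k sweep and
  the coverage score reproduce their selection behavior, and on planted
  monomers the walk recovers the exact circular sequence (up to rotation
  and strand, which is all a circular consensus defines). The coverage
  denominator includes *all* k-mers, noise included; restricting it to
  above-noise k-mers would raise the score but needs a noise model the
  data does not pin down.
* **5S graph type** — 5S arrays alternate a conserved ~120 bp gene with a
  variable intergenic spacer (IGS); distinct IGS "ribotypes" mark distinct
  loci/subgenomes, and in cluster-graph layouts they appear as loops joined
  at the conserved gene. We count loops by the testable formalization:
  reads matching the gene exemplar (>= 80% identity over >= 40 bp) are set
  aside, the remaining IGS reads are re-clustered under the standard
  90%/55 contract, and each IGS sub-cluster holding at least 5% of the
  cluster's reads is one loop; graph type = loop count clamped to 1–3
  (type 1 = simple circle, types 2/3 = two/three loops). The 5% occupancy
  floor keeps singleton chimeric reads from minting spurious loops; the
  80%/40 gene thresholds sit well below the within-gene conservation and
  well above chance similarity.

## Hs/Ho diversification landscape

For every read in an annotated cluster, `Hs` counts its hits to
same-sample reads and `Ho` its hits to other-sample reads, normalized as
`Ho_norm = Ho_raw (n_s - 1) / n_o` with `n_s`, `n_o` the analysed read
totals — the expected hit count is proportional to the number of available
partner reads, so this makes Hs and Ho comparable under unequal coverage
(duplicating the other sample's reads leaves `Ho_norm` invariant, which the
tests assert). Conserved families give log10(Hs/Ho) near 0; families that
diversified between samples lose cross-sample hits and shift positive.
Reads with `Hs = 0` or `Ho_raw = 0` are excluded from the histograms and
counted separately — a pseudo-count would fabricate ratios, and the
excluded count is exactly how sample-private repeats show up. Histograms
use fixed 0.1-wide bins on [-3, 3] with out-of-range ratios clamped into
the edge bins; note 0 falls on a bin edge, so a perfectly conserved family
peaks in a bin centered at ±0.05.

## Per-cluster phylogenies and the consensus network

For each top cluster the inter-sample edge counts are compared with a
uniform random-placement model: with per-sample node counts $n_s$, cluster
edge count $E$ and $P$ total node pairs, $\mathrm{exp}(s,t) = E n_s n_t /
P$ (within-sample: $E\,n_s(n_s-1)/2P$), and the observed/expected ratio
measures how much more (or less) similar two samples' reads are than
random mixing. Matrices missing a sample or containing a zero off-diagonal
ratio are excluded rather than patched — an absent similarity is not an
infinite distance estimate. Surviving matrices become distances via
$d = 1/\mathrm{obs\_exp}$ (off-diagonal only; the diagonal is zero by
definition and within-sample similarity does not enter the transform).

Neighbor joining is the classical Q-criterion agglomeration with the
standard branch-length formulas. Ties in Q join the lexicographically
smallest label pair, so the tree is a deterministic function of the input;
negative branch estimates are clamped to zero with the deficit shifted to
the sister branch, preserving the joined pair's path length. On additive
matrices the reconstruction is exact (tested to 1e-9 against tree metrics
and cross-checked topologically against the reference NJ implementation in
`ape`).

The consensus network decomposes every per-cluster tree into splits,
keeps splits whose support (fraction of trees) reaches `min_support`
(default 0.1, standing in for split-network defaults), weights each by its
mean branch length, and writes a NEXUS splits block consumable by split
-network viewers. Trivial splits are always present.

## Genome-size statistics

Per-lineage abundance (Mbp/1Cx) is correlated with monoploid genome size
(Pearson, $R^2$ and the t-transform p on n−2 df). The average contribution
of a repeat to pairwise genome-size differences is reconstructed as: over
all sample pairs with $GS_i > GS_j$,
$c = (A_i - A_j)/(GS_i - GS_j) \times 100$, negatives floored at zero,
averaged. The flooring is a modelling choice: published tables report 0%
contributions for lineages that are positively correlated with genome size
but locally anti-vary across pairs, which a signed mean cannot produce;
the signed variant stays available via `floor_negative = FALSE`. Group
differences use the tie-corrected Kruskal–Wallis test (`stats::
kruskal.test`; fully tied data are reported as H = 0, p = 1). p-values are
reported raw, with no multiple-testing correction.

## The synthetic-data generator

`synthkit` emulates what the pipeline consumes: multi-sample, multi-ploidy
genomes with dispersed repeat families (tunable copy number and per-copy
divergence), tandem satellite arrays, and 5S arrays of a conserved gene
plus ribotype-specific spacers. Copies are planted at uniformly random
non-overlapping positions in random background; substitution-only
mutation keeps planted base counts exact, so truth proportions are exact
by construction. Polyploids are multiset unions of monoploid sequences.
Reads are 2x101 bp pairs with uniform insert length on [123, 329] bp
(the observed range of the motivating datasets), uniform fragment
placement, substitution errors at a default 0.5% (a free choice in the
realistic Illumina range; error profiles are not modelled), and headers
carrying a fixed 4-character sample code — the convention that makes
sample recovery from comparative clusterings trivial. All randomness flows
from one integer seed through a deterministic splitting function
(`derive_seed`), so identical specs give byte-identical FASTA/FASTQ.

What the generator does **not** emulate: quality-score structure, PCR
duplicates, GC bias, indel errors, nested/fragmented repeat insertions,
chromosome-scale karyotype structure (no dysploid fusions), and real
repeat-library phylogenetic structure. Passing tests on these simulations
therefore demonstrates the correctness of the graph arithmetic and the
recoverability of planted signal under clean sampling — not robustness to
library artifacts of real skim data.

## Benchmark scenarios and problem sizes

The bundled `scenario_*` functions freeze the study conditions used by the
test suite and the reproduction script:

* **Oracle equivalence** — 200 reads from a two-family genome; seeded
  finder vs brute-force scan, exact equality.
* **Planted proportions** — 3 samples, ~10 Mbp monoploid genomes, five
  families at ~25/10/5/2/1% (two LTR-Gypsy, one LTR-Copia, one tandem
  satellite, one DNA transposon; 2–4% copy divergence), skimmed at 0.1x
  (~9,900 reads/sample). Estimates are scored as binomial z-scores against
  exact truth; the acceptance band is |z| <= 3 for all 15 sample×family
  cells.
* **5S typing** — 1–3 ribotypes, 60 units per array, 0.3x coverage;
  20 seeded runs per ribotype count, requiring >= 18/20 correct types.
* **Hs/Ho** — two samples, four conserved + four 8%-diverged 2 kb
  families (40 copies each), 0.4x coverage, two pooled replicates.
  Several independent families per lineage matter here: consensus
  divergence is positional, so a single family's locally conserved
  windows dominate the cross-sample hit tail and make the histogram mode
  unstable; pooling families averages that heterogeneity out.
* **Species network** — six samples on a fixed 6-leaf tree (unit terminal
  branches, internal edges 2–3 units, 0.8% substitutions per unit), twelve
  1.5 kb families evolved along the tree, 0.3x coverage; the consensus
  network must contain all three internal splits of the truth at support
  >= 0.5 in at least 8 of 10 seeded runs.

These sizes keep each scenario in the seconds-to-a-couple-of-minutes range
on one CPU while leaving enough reads per cluster for the statistics to be
non-degenerate.

## Known limitations

* The hit verifier is quadratic in local read density; satellite-heavy
  datasets at high coverage inflate candidate pairs (real pipelines cap
  this with sampling, as does the coverage ceiling of 0.5x here).
* Cluster = connected component means chimeric bridges can merge families;
  the Louvain refinement flag exists but is intentionally off by default.
* The greedy circular walk can shortcut through long-period satellites
  with internal sub-repeats at small k; the coverage-maximizing k sweep
  mitigates but does not eliminate this.
* The observed/expected model assumes exchangeable edge placement within a
  cluster; strong within-sample substructure (e.g. two subfamilies private
  to one sample) biases the diagonal and, mildly, the off-diagonal ratios.
* One published 1Cx table entry (the annual allotetraploid hybrid) is
  internally inconsistent with its own 2C/nx rule and in-text Mbp figures;
  the bundled table keeps the printed value and the tests document the
  discrepancy rather than silently correcting it.
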