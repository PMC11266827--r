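Package: skimrep
Title: Repeatome Quantification and Phylogenomics from Genome-Skimming Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale repeatome analysis of low-coverage (genome-skimming)
    paired-end sequencing data. Builds the all-vs-all read-similarity graph
    under an explicit ungapped overlap contract (90 percent identity over at
    least 55 bp by default), extracts repeat clusters, annotates them against
    a labelled repeat library, and converts cluster sizes into genome
    proportions and Mbp amounts per monoploid genome. Tandem (satellite and
    5S rDNA) clusters are characterized by a connected-component index, a
    k-mer consensus with coverage score, and 5S graph typing by intergenic
    spacer (IGS) loop counting. Cross-sample comparisons include per-read
    intraspecific versus interspecific hit ratios (Hs/Ho), per-cluster
    observed/expected edge matrices turned into inverse-similarity distances,
    neighbor-joining trees and their consensus split network, and
    repeat-abundance versus genome-size statistics. A seeded synthetic-data
    generator plants repeat families, polyploid subgenomes and 5S ribotype
    arrays with exact ground truth so the whole pipeline is testable without
    external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    igraph,
    ape,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
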