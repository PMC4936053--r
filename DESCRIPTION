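Package: guildomics
Title: Comparative Genomics of Gut Bacterial Trophic Guilds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of the comparative-genomics workflow
    used to characterise uncultured gut Bacteroidales families from draft
    (population) genomes: carbohydrate-active enzyme (CAZy) profiling and
    trophic-guild inference by the intersection of an indicator-value
    statistic with pairwise negative-binomial differential abundance;
    detection of polysaccharide utilisation loci anchored on susC/susD gene
    pairs; gene-set presence/absence census with contig-boundary flags;
    fragment-based average nucleotide identity (Goris method) and reciprocal
    best-hit average amino acid identity with single-linkage species/genus
    partitioning; Faith's phylogenetic diversity on gene trees; and
    read-mapping prevalence and relative abundance estimation. A synthetic
    data module generates genome annotations, sequence pairs, trees and
    coverage tables with known ground truth so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    vegan,
    igraph,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    picante,
    mclust,
    rtracklayer,
    GenomeInfoDb
Config/testthat/edition: 3
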