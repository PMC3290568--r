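Package: standscan
Title: Selection Scans and Neutrality Tests for Standing-Variation Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the selective signature of a resequenced
    candidate locus from phased haplotypes: classical summary statistics
    (segregating sites, nucleotide diversity, Watterson's theta, Tajima's D),
    pairwise linkage disequilibrium (D, |D'|, r^2) with complete-LD grouping,
    a Hudson-style coalescent simulator with crossover and gene conversion
    under explicit demographic models for null distributions and 97.5th
    percentile neutrality tests, EHH/iHS haplotype-based selection scans,
    allele-age estimation from the decay of haplotype sharing, Kendall rank
    correlation of allele frequencies with pathogen richness, and
    counting-based (NG86) dN/dS with lineage assignment of codon changes.
    A synthetic-data module generates neutral samples, partial sweeps,
    environmental-correlation tables and codon alignments with known truth,
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stringr,
    igraph,
    yaml,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
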