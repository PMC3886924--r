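Package: coenokaryo
Title: Single-Nucleus Sequencing Analysis of Karyotype Homogeneity in
    Coenocytic Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for deciding whether the many nuclei of a
    coenocytic (multinucleate) fungus are homokaryotic or heterokaryotic from
    short-read sequencing of amplified single nuclei and bulk mycelium. It
    simulates multinucleate genomes with MDA-biased paired-end reads and known
    ground truth, builds multi-sample (colored) de Bruijn graphs, performs
    reference-free bubble calling of SNPs and indels at two k values with
    per-sample genotyping, computes reference-based variant counts and an
    aligned-identity statistic, quantifies per-site polymorphism across a
    multi-copy rDNA-like repeat unit, and integrates all evidence into a
    karyotype verdict. Assembly utilities provide unitig extraction, read-pair
    scaffolding, length filtering and N20/N50/N80 statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
SystemRequirements: C++17
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
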