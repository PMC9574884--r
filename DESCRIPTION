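Package: ampliphase
Title: Multiplexed Long-Read Amplicon Genotyping of Adjacent Tandem Repeats
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted long-read amplicon sequencing of loci carrying
    two adjacent tandem repeats, with the huntingtin (HTT) exon-1 CAG/CCG
    locus as the canonical instance. Provides dual-barcode design under
    cross-hybridization constraints with maximal-clique selection,
    anchor-aware demultiplexing with Phred-scaled barcode mapping quality,
    per-read joint quantification of two repeat sizes by decoy-based bound
    estimation and exhaustive template-grid refinement, diploid allele
    phasing with a jitter-stabilized Gaussian mixture model, per-allele
    pileup consensus SNP calling, SNP-mediated PAM gain/loss classification
    for allele-specific CRISPR editing, haplotype frequency tables, and a
    seeded nanopore-like read simulator with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    igraph,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, Genetics, VariantDetection, CRISPR
RoxygenNote: 7.3.3
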