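Package: meripr
Title: MeRIP-Seq Peak Detection and Comparative m6A Methylome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for transcriptome-wide N6-methyladenosine (m6A) profiling
    from MeRIP-Seq coverage data. Implements Poisson local-background
    enrichment peak calling of immunoprecipitated (IP) versus input
    libraries, replicate-recurrence filtering and common/specific peak
    classification between conditions, strand-aware transcript coordinate
    systems with six-segment annotation (5'UTR, start codon, CDS, stop
    codon, 3'UTR, other), metagene profiling, RRACH motif enrichment
    against dinucleotide-preserving shuffles, M-A normalised dynamic-peak
    detection with an exact conditional test, RPKM-based differential
    expression, and methylation-expression association tests. Ships a
    synthetic MeRIP-Seq generator with planted ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
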