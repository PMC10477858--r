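Package: phageMethylome
Title: Community-Scale Analysis of Gut Phage DNA Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing DNA methylation of bacteriophage communities
    from single-molecule base-modification calls: rule-based viral contig
    recognition by evidence voting, methylation-density statistics with
    coding/non-coding splits and prevalence-density partial correlation,
    IUPAC degenerate methylation-motif algebra (subsumption, dereplication,
    genome scanning, support filtering), DNA methyltransferase (MTase)
    annotation with orphan-enrichment testing and Markov clustering of
    protein families, and MTase-homology phage-host prediction with
    last-common-ancestor host ranges. Includes a fully seeded synthetic
    phage-bacterium community generator with planted methylation, MTase
    homology and host links, so the entire pipeline is testable end to end
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
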