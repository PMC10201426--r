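Package: isoedit
Title: Isoform-Resolved A-to-I Editome and RIP-Seq Peak Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for comparing the editing and binding
    preferences of the two ADAR1 isoforms (cytoplasmic ADAR1p150 and nuclear
    ADAR1p110). Classifies known A-to-I editing sites into isoform-preference
    categories from per-replicate editing tables (control subtraction,
    rate/coverage/replicate-consistency filters, efficiency calls, a log2
    fold-difference statistic, Welch tests with Storey q-values, gene-region
    and repeat-class annotation), post-processes RIP-seq enrichment peaks
    (strand-split calling with an internal Poisson caller, replicate adjacency
    consensus, fractional MOCK subtraction, priority annotation), quantifies
    amplicon deep-sequencing editing with max-normalization, and intersects
    sites, peaks and gene sets. Includes a seeded synthetic-data generator that
    emulates the study design (three replicates per isoform plus negative and
    MOCK controls) with a planted ground-truth manifest for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
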