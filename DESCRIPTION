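Package: p53occupancy
Title: Differential Occupancy of Total and Phospho-Specific p53 by ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline comparing genome-wide chromatin binding of
    total p53 and its Serine-15/Serine-46 phosphorylated forms across two
    stress treatments, and integrating binding with expression changes.
    Covers library normalization by uniform read removal, directional tag
    extension and window-averaged coverage, local-Poisson peak calling,
    reads-per-peak occupancy comparison (R-squared, common/preferential
    classification, Kolmogorov-Smirnov tests, quintile modification
    fractions), five-category genomic region annotation, bipartite p53
    response-element motif scanning, expression-ratio integration with
    uncentered-correlation k-means clustering, and selection of candidate
    genes differentially bound by phospho-S46 p53. Includes a truth-annotated
    synthetic study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
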