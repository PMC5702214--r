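Package: clonotrace
Title: Clonal Architecture from Single-Cell Amplicon Resequencing of SNVs and
    Structural-Variant Breakpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotypes bulk-confirmed single-nucleotide variants and
    structural-variant breakpoint junctions in amplicon-resequenced single
    cells using explicit read-count thresholds, assembles a binary
    cell-by-mutation matrix under coverage-based cell quality control, infers
    clonal populations with a mixture of multivariate Bernoulli distributions
    fit by expectation-maximization, and reconstructs the clonal architecture
    as a minimal spanning tree over clone consensus genotypes. Includes a
    simulator of single-cell amplicon data (allelic dropout, false positives,
    doublet cells, poor assays) with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
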