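Package: phenoscreen
Title: Phenomic and Genomic Screening Toolkit for Rosette Morphometrics and
    Flower-Related Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based plant phenomics and companion genomic
    screens. Computes nine rosette shape descriptors (area, perimeter,
    roundness, roundness 2, isotropy, eccentricity, rotational mass symmetry,
    compactness and slenderness of leaves) from binary top-view masks;
    compares genotype growth trajectories with nested polynomial models and
    likelihood-ratio chi-square tests; analyses flowering time with
    Dunnett-adjusted many-to-one comparisons and flower-defect contingency
    tables; screens expression matrices for flower-enriched genes by log2
    fold change; quantifies qPCR data by the 2^-ddCt method; locates and
    classifies canonical RING zinc-finger domains; and generates fully
    synthetic inputs with known ground truth for every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    grDevices,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    multcomp,
    Biostrings,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
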