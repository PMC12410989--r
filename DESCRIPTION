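Package: celltempo
Title: Cell-Type Abundance and the Tempo of Neuronal Gene Expression Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating neuronal cell-type abundance to cross-species
    gene-expression divergence in single-nucleus RNA-seq data. Implements
    downsampling-equalized pseudobulk divergence estimation between species,
    correlation of per-cell-type divergence with cell-type proportions,
    three-taxon parsimony decomposition of pairwise divergence onto lineage
    branches using an outgroup, gene stratification by expression level,
    cell-type specificity (tau) and constraint (s_het) with expression-matched
    pairing, within-species interindividual variability, and directional
    binomial sign tests with empirical backgrounds for detecting polygenic
    lineage-specific selection on gene sets, including allele-specific
    expression from interspecies hybrid cells. A synthetic-data generator
    with planted ground truth supports end-to-end parameter-recovery and
    calibration testing without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
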