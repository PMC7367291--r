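Package: sugibs
Title: Robust Genome-Wide Ancestry Inference via Spectral Decomposition
    of an Unnormalized Genomic Relationship Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs reference ancestry spaces from genome-wide SNP
    genotypes by a generalized spectral decomposition of the unnormalized
    genomic relationship matrix, normalized by identity-by-state (IBS)
    similarity degrees (SUGIBS), and projects new samples onto such spaces
    with a per-individual reference-degree correction that is robust to
    missing genotypes and genotyping errors.  Includes PLINK 1 binary
    input/output, dataset harmonization and variant filtering, comparator
    methods (PCA on normalized genotypes, unnormalized PCA, classical MDS
    on IBS distances), Balding-Nichols-style drift and admixture
    simulators, a case-control stratification simulator, a vectorized
    logistic likelihood-ratio association scan, and evaluation harnesses
    for outlier robustness, projection robustness, and stratification
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
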