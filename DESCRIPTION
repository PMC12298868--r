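Package: germcore
Title: Core Germplasm Construction and Evaluation for Crop Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of core germplasm collections from
    phenotypic and genotypic data. Implements trait diversity statistics
    (coefficient of variation, Shannon-Weaver diversity index, PCA), a
    generalized Lance-Williams agglomerative clustering engine covering eight
    classical linkage methods, stepwise cluster-based core sampling over a
    strategy grid (distance x ratio x allocation x linkage) with MD/VD/CR/VR
    evaluation, SNP diversity statistics (He, Ho, Shannon information index,
    genetic similarity coefficients, SNP density), Evanno delta-K
    post-processing of STRUCTURE-style likelihood tables, genotypic core
    selection by entry-to-nearest-entry distance maximization, integration of
    phenotypic and genotypic cores, and membership-function scoring for
    germination-stage salt-alkali tolerance classification. Includes
    synthetic-data generators (Gaussian-copula phenotypes, Balding-Nichols
    structured genotypes, latent-group stress indicators) so the full
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    ape,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
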