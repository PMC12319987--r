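Package: latnet
Title: Surface-Area-Based Lateralization of Cortical Functional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies hemispheric lateralization of cortical functional
    networks from labeled surface meshes using the network surface area
    ratio (NSAR), the relative difference between a network's right- and
    left-hemisphere surface areas. Provides readers and writers for GIFTI
    and FreeSurfer surface and label formats, Hungarian matching of
    individual parcels to a reference network scheme, dice overlap,
    covariate adjustment of lateralization values, an autonomy index for
    convergent validity, test-retest reliability tools (two-session ICC,
    incremental-data stability, exact Wilcoxon signed-rank tests),
    Bonferroni-controlled identification of lateralized networks, and the
    factor-analytic machinery (Bartlett sphericity, KMO, Doornik-Hansen,
    VIF, iterated principal-axis factoring, parallel analysis, and
    maximum-likelihood confirmatory factor analysis) used to test whether
    left- and right-lateralized networks covary across individuals. A
    synthetic-data module generates populations with known lateralization
    structure, rendered icosphere parcellations, run-level perturbations,
    and block-structured connectivity so every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
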