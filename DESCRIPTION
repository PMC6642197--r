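Package: digitid
Title: Comparative Transcriptomics of Digit Identity in Amniote Limbs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable analysis pipeline for testing whether digits of
    amniote limbs carry conserved developmental identities, based on bulk
    RNA-seq of digits and their posterior interdigital mesenchyme. Provides
    TPM normalization with square-root variance stabilization and bulk
    mean-centering, negative-binomial GLM likelihood-ratio tests for
    adjacent-digit and any-digit contrasts with Cox-Reid dispersion
    estimation and BH/Storey FDR control, correlation-dissimilarity
    average-linkage clustering with gene-bootstrap support, centered PCA
    with supplementary-sample projection and digit-correspondence calling,
    cross-species conservation statistics (ortholog-restricted DE-set
    intersections, binomial overlap nulls, expression-matched fold-change
    correlations), and a negative-binomial count simulator with planted
    digit-identity modules for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
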