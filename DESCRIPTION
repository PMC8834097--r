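Package: cytosig
Title: Multivariate Cytokine Signature Analysis for Case-Control Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multiplexed cytokine/chemokine concentration panels
    (e.g. Luminex) in case-control and clinical-severity designs. Implements
    z-scored discriminant and continuous partial least squares regression
    (NIPALS, two latent variables) with orthogonal rotation of the latent
    space, leave-K-out cross-validation of loading stability, rank-based
    univariate screens (Dunn's test with Bonferroni correction, Wilcoxon rank
    sum with exact enumeration for small samples), iterative principal
    component / Mahalanobis outlier rejection, cross-dataset coincident
    signature selection and signature projection across species and tissue
    compartments, plus a latent-factor log-normal generator of synthetic
    cytokine cohorts with planted effects and linked ordinal clinical scores.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
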