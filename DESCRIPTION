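Package: metaboBench
Title: Benchmarking Univariate and Sparse Multivariate Association Methods
    for High-Dimensional Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-based comparison of statistical approaches for
    identifying metabolites associated with clinical outcomes in
    high-dimensional metabolomics studies. Provides a synthetic-data
    generator with block-structured between-metabolite correlation (mean
    pairwise correlation +0.40), six association methods (univariate scans
    with Bonferroni or Benjamini-Hochberg correction, principal component
    regression, LASSO, sparse partial least squares and its discriminant
    variant, and random forest), operating-characteristic evaluation
    against planted truth (sensitivity, specificity, PPV, NPV, false
    positive counts), a full scenario grid over sample size, metabolite
    number, and outcome type, and a cohort-style analysis stage
    (log/z-score preprocessing, method set overlap, thresholded Spearman
    correlation networks with JSON and GraphML export).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    ranger,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
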