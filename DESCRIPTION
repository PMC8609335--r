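Package: hyperMVPC
Title: Between-Subject Identity Decoding with Searchlight Hyperalignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for between-subject multivariate pattern classification
    (MVPC) of face identity on cortical surface data. Implements searchlight
    hyperalignment (generalized Procrustes alignment of subjects' response
    patterns into a common model space estimated from movie-watching time
    series), nested cross-validation of linear support-vector classifiers
    across both participants and stimulus head views, permutation and
    bootstrap null distributions with Benjamini-Hochberg FDR control,
    carry-over counterbalanced (Type-1 Index-1) trial sequence design,
    GLM estimation of condition response patterns, and a synthetic
    multi-subject data generator with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
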