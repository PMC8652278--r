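Package: strucomp
Title: Structural Comparison of Similarity Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two (dis)similarity matrices defined over the same set of
    subjects by learning a low-complexity structure from a reference matrix
    (truncated eigendecomposition or a simplex-constrained mixture factorization
    Y ~ A X A'), predicting the target matrix conditional on that structure with
    a freely refit relationship, and summarising the residuals that persist
    across a sweep of model complexities. Includes split-half resampling based
    significance for residual persistences, cross-validated complexity
    estimation, a coalescent-tree/Brownian-motion trait simulator and a
    methylation-expression case-control simulator with planted anomalies, plus
    ggplot2 persistence charts and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
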