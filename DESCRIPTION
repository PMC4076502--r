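Package: exacttrend
Title: Exact Joint Testing of a SNP Under Additive, Dominant, and Recessive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control association testing of a di-allelic SNP with the
    Cochran-Armitage trend test under the additive, dominant, and recessive
    genetic models, together with an exact p-value that corrects for testing
    the three models jointly. The three unnormalized trend statistics are
    functionally dependent, so their exact joint null distribution lives on a
    two-dimensional integer lattice; the package enumerates that lattice
    (a pattern of overlapping triangles indexed by the control genotype
    configuration), computes the joint probability mass function from
    trinomial convolutions, and returns the probability-ordering exact
    p-value. Per-model asymptotic tests, the min-p and Bonferroni baselines,
    a simulation harness for type-1-error and power experiments under a
    logistic disease model, and delimited-file readers and a command-line
    interface are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
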