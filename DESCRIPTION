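Package: iseseg
Title: Meiotic Transmission Analysis of Independently Segregating Genomic Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and infers meiotic transmission biases of independently
    segregating genomic elements (ISEs; supernumerary B-chromosome-like
    elements) from genome-size distributions of haploid rotifer males. Provides
    an exact two-parameter segregation model (transmission bias and
    cosegregation bias) with a Monte-Carlo oracle, grid-search least-squares
    estimation of the two parameters with the full RMSE surface, skew-normal
    finite-mixture decomposition of one-dimensional flow-cytometry fluorescence
    histograms into genome-size class proportions with BIC model selection and
    background exclusion, replicated G-tests of goodness-of-fit (total, pooled
    and heterogeneity components), and a synthetic-data generator that emulates
    flow-cytometry samples so the whole pipeline is testable without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
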