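Package: polyrec
Title: Recombination Frequency and Double Reduction from Fluorescent-Seed
    Phenotype Counts in Polyploid F2 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of meiotic recombination frequency
    between two dominant fluorescent seed markers from four-class phenotype
    counts (yellow, green, red, grey) in F2 populations of diploid,
    allotetraploid (disomic) and autotetraploid (tetrasomic) plants. Implements
    the disomic and tetrasomic phenotype-class probability models, a two-step
    estimator of the coefficient of double reduction and the recombination
    fraction under tetrasomic inheritance, observed-information standard
    errors, likelihood-ratio comparisons of point estimates, a moment
    (proportion) comparison estimator, and a multinomial simulator with a
    parameter-recovery harness for validating estimator and standard-error
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
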