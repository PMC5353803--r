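Package: microtax
Title: Multinomial K-mer Taxonomy Classification for 16S rRNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genus-level taxonomic classification of 16S rRNA gene sequences
    using a multinomial K-mer model with streaming posterior log-probability
    scoring, together with two complementary measures of classification
    uncertainty: a length-normalized d-score that flags sequences near a
    decision boundary, and a genus-standardized r-score (with loess-smoothed
    variance shrinkage and an empirical cumulative distribution function)
    that flags sequences unlike anything in the training data. Includes a
    bootstrap-free naive-Bayes word-presence classifier for comparison, a
    synthetic 16S community generator with read-fragment and sequencing-error
    simulation, and evaluation tools for read-length, unknown-taxon and
    corruption experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
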