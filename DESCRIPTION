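Package: myolabour
Title: Transcriptome Analysis of Labouring Versus Non-Labouring Myometrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for two-group bead-array transcriptome studies of
    the myometrium at term, built around the comparison of labouring and
    non-labouring uterine smooth muscle. Provides a synthetic-data generator with
    an explicit smooth-muscle/leukocyte tissue-composition ("dilution") mixture
    model and known ground truth; normexp background correction, quantile
    normalisation and negative-control detection-floor filtering; rank-product
    differential expression with permutation-based percentage-of-false-positives
    (PFP) correction; thresholded Pearson correlation networks over samples and
    probes clustered with a from-scratch Markov Clustering (MCL) implementation;
    subgroup sensitivity analysis; delta-CT qRT-PCR comparison; and fixed- and
    random-effects standardised-mean-difference meta-analysis across studies with
    heterogeneity statistics and cross-study concordance reports. All user-facing
    functions take data frames and return tibbles.
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
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
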