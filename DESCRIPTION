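Package: smybpc
Title: Splice-Variant Catalog and Single-Fiber Expression Profiling for Slow
    Myosin Binding Protein-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the family of slow Myosin Binding
    Protein-C (sMyBP-C) proteoforms produced by alternative splicing of the
    MYBPC1 transcript. Provides a machine-readable catalog of the 14 human and
    2 mouse full-length variants with the cassette-exon grammar of the
    NH2-terminal Pro/Ala region, the M-motif, domain C7 and the COOH-terminal
    tail; rule-based annotation of predicted phosphorylation sites, sarcomeric
    localization and actomyosin interaction class; a delta-mass model that
    predicts variant molecular weights from exon composition and partitions
    variants into six molecular-weight groups; a ladder-calibrated SDS-PAGE
    band-sizing pipeline that assigns immunoreactive bands to those groups;
    single-fiber expression-pattern tallying with myosin-isoform association;
    and a synthetic-data generator that reconstructs published soleus and
    FDB single-fiber datasets and simulates noisy gels with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
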