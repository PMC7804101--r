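Package: covershape
Title: Shape-Change Outlier Detection in Base-Level RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents each sample's per-base RNA-seq read coverage over a
    gene as a high-dimensional vector, normalises out depth- and
    expression-dependent structure with a multiplicative model, and flags
    samples whose coverage shape is an outlier using a modified projection
    outlyingness statistic with a normality-screened direction search.
    Detection proceeds in two steps: global shape changes on an orthogonal
    exon/intron basis and local shape changes on sparse window directions in
    the residuals. Each call's most outlying direction is combined with
    splice-junction evidence to type the event (exon skipping, intron
    retention, deletion, alternative transcription start/termination,
    over/under-expression). Includes cohort quality-control filters for
    3'-biased RNA degradation and on/off genes, and a synthetic-cohort
    generator with injected events and truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    GenomicAlignments,
    MASS,
    nortest,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
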