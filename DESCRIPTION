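Package: dormantx
Title: Intrinsic Immune Landscape of Castration-Induced Dormant Prostate
    Cancer Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the intrinsic immune landscape of
    castration-induced dormant prostate-cancer patient-derived xenografts
    (PDX) from bulk RNA-seq. Provides species partitioning of reads
    aligned to a combined human+mouse reference, gene-level
    quantification with TPM and median-of-ratios normalization, per-model
    dormant/active fold changes, threshold-consensus gene filters
    (expression, consensus differential expression across paired models,
    dormancy persistence), immune gene-group annotation and signature
    comparison, random-forest discriminative gene selection, and
    Ward.D2/Canberra hierarchical clustering, together with a
    negative-binomial simulator that plants ground-truth effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ranger,
    ape,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    DESeq2,
    knitr,
    rmarkdown,
    withr,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
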