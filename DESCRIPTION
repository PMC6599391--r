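Package: specscreen
Title: Design and Analysis of Synthetic Promoter Sort-Seq Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for synthetic promoter screens that couple
    fluorescence-activated cell sorting into expression bins with
    next-generation sequencing of each bin (sort-seq). Designs barcoded
    tandem-repeat promoter libraries from transcription-factor binding-site
    motifs, simulates the binned screen (five-gate sorting, multinomial
    sequencing counts, replicate noise), preprocesses raw reads into
    normalized count tables (restriction-site filtering, read collapsing,
    reference matching, median-of-ratios size factors, replicate filtering),
    estimates promoter activity with a weighted-average bin score and a
    cross-validated elastic-net regression on engineered count features,
    ranks promoters by cell-state specificity, and computes pixel-intensity
    distribution heat maps for imaging time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    glmnet,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    DESeq2,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
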