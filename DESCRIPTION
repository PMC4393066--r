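Package: gcdomains
Title: Compositional Domain Segmentation of Genomes by Recursive
    Jensen-Shannon Divergence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Partitions chromosome- and scaffold-scale DNA sequences into
    compositional domains by recursive binary segmentation of GC content
    using the Jensen-Shannon divergence, with a dynamic, length-calibrated
    halting criterion.  Assembly gaps (N islands) are mapped, removed before
    segmentation, and restored afterwards by a mask-or-split rule; each
    inferred domain is tested for compositional homogeneity against its host
    sequence with a one-sided variance-ratio test, classified by length and
    GC band, and reported as a tidy table.  Includes ideogram and
    distribution graphics, a mosaic-genome simulator with exact-GC mode for
    benchmarking, and a batch pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
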