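Package: hetstab
Title: Suppressor Mapping and Heterochromatin Over-Replication Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for the genomics of heterochromatin
    instability phenotypes: pooled-bulk EMS suppressor mapping by allele
    frequency (binomial enrichment testing, sliding-window mismatch profiles,
    candidate-interval calling, and variant-effect classification),
    read-depth copy-number ratio tracks with a permutation test for
    pericentromeric gain, RPKM quantification with negative-binomial
    up-regulation calling and Fisher set-overlap tests, windowed
    differentially-methylated-region discovery from bisulfite cytosine
    reports, and constrained Gaussian-mixture fitting of flow-cytometry
    ploidy histograms with per-peak coefficient-of-variation readouts.
    Every analysis stage is paired with a seeded synthetic-data generator
    that plants machine-readable ground truth, so recovery can be verified
    end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
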