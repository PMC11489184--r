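Package: meadev
Title: Developing Neuronal Network Activity on Multi-Well Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chronic-exposure developmental neurotoxicity
    screens on multi-well microelectrode arrays (MEA). Detects spikes from raw
    extracellular traces (band-pass filter, robust noise estimate, adaptive
    threshold), single-electrode bursts by the Poisson-surprise method, and
    well-level network bursts with an adaptive maximum inter-spike interval;
    computes ten per-well activity parameters including cross-correlation
    synchrony; normalizes developmental time courses as cumulative treatment
    ratios against solvent-control wells; applies per-condition outlier
    exclusion, benchmark-response banding, and one-/two-way ANOVA with Tukey
    post-hoc tests to flag concentration- and sex-specific effects and summarize
    lowest-observed-effect concentrations. Includes a stochastic generator of
    developing, bursty, partially synchronized spike-list datasets so the whole
    pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
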