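Package: circaflux
Title: Circadian Analysis of Bioluminescence Recordings and Rhythmic
    Transcriptomes Under Cyclic Metabolic Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing circadian oscillations in Per2::Luc
    bioluminescence time-lapse recordings and in rhythmic gene-expression
    time courses. Converts image stacks into region-of-interest traces
    after selective-median cosmic-ray removal, detrends traces by running
    averages, estimates period and phase by damped-sine fitting and by
    the Hilbert analytic signal, quantifies population synchrony with the
    Kuramoto order parameter, and summarizes acrophases with circular
    statistics. Includes a from-scratch implementation of the JTK_CYCLE
    nonparametric rhythmicity test with an exact permutation null,
    together with downstream transcriptome summaries (cpm filtering,
    rhythmic-gene selection, day/night phase binning, phase-ordered
    heatmap scaling, set overlaps, and an ANOVA rule for differential
    mean expression). A synthetic-data module generates traces, image
    stacks, feeding-fasting protocol schedules, metabolite-concentration
    curves, and negative-binomial count matrices with known ground truth.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
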