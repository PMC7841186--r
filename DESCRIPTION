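Package: benchrank
Title: Ranking Stability Analysis and Visualization for Benchmark Challenges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis and visualization of benchmark challenge results for
    single- and multi-task competitions. Computes algorithm rankings under
    aggregate-then-rank, rank-then-aggregate and test-based (one-sided
    Wilcoxon signed-rank with Holm adjustment) schemes with the min-rank tie
    convention, quantifies ranking stability by bootstrap resampling of test
    cases (rank distributions, percentile intervals, Kendall's tau to the
    full-data ranking) and cross-task robustness (consensus rankings, rank
    distance measures, task clustering), and renders the associated figure
    family: dot-and-box, podium, ranking heatmap, line, blob, violin,
    significance map, dendrogram and network plots. Includes synthetic
    challenge generators for fully separated and fully random scenarios and a
    report driver producing a complete, reproducible analysis bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    ggplot2,
    rlang,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
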