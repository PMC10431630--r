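Package: tsgraph
Title: Graph-Represented Time Series for Subsequence Anomaly Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised detection of subsequence anomalies (discords) in
    univariate time series via a weighted directed graph representation.
    All sliding-window subsequences are z-normalized, embedded into a 2D
    spatial-temporal space with principal component analysis, and binned
    onto a regular grid; consecutive windows define weighted transitions
    between grid cells (including self-loops).  Each subsequence is scored
    by the mean edge weight along its path through the graph, so rare
    waveforms - single or recurrent - receive low scores.  Includes a
    synthetic quasi-periodic signal generator with planted anomalies, a
    brute-force nearest-neighbor discord baseline for comparison, report
    and graph export in plain-text formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
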