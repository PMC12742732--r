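Package: topobind
Title: Topological EEG Features and Intentional Time Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of the relation between self-reflection,
    the implicit sense of agency, and topological structure of EEG
    time series. Provides a synthetic-data module (band-structured EEG
    with 1/f background, line noise and muscle artifact; Libet-clock
    trial schedules with injectable perceptual shifts), EEG
    preprocessing (zero-phase FIR band-pass and notch, ICA-based
    muscle-component screening, channel pooling, segment extraction,
    decimation), spectral band powers via Welch's method, Takens delay
    embedding with Vietoris-Rips persistent homology (diagrams, Betti
    curves, persistence entropy, Wasserstein amplitude), Hodge-Laplacian
    spectral entropy, multiscale sample entropy, intentional
    time-binding scoring, and the nonparametric statistical battery
    (Shapiro-Wilk gating, one-tailed Mann-Whitney, Kruskal-Wallis with
    epsilon-squared, Pearson correlation, Wilcoxon power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    signal,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
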