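Package: nigraspace
Title: ROI-Based Spatial Transcriptomics of the Substantia Nigra with
    Network Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for region-of-interest (ROI) spatial
    transcriptomic profiling of the substantia nigra pars compacta in
    Parkinson disease and the Parkinsonian subtype of multiple system
    atrophy. Provides ROI quality filtering, between-lane normalization,
    removal of unwanted variation from empirical control genes,
    negative-binomial Wald differential expression with
    Benjamini-Hochberg adjustment, over-representation analysis with
    Enrichr-style combined scores and redundancy-reducing term
    clustering, quadrant-stratified contrasts and DEG-overlap summaries,
    and hub-gene identification by random-walk-with-restart network
    propagation combined with betweenness centrality on a
    protein-protein interaction network. Includes a synthetic-data
    generator with known ground truth for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
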