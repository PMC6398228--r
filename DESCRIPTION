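Package: profassess
Title: Assessment and Ranking of Taxonomic Metagenome Profilers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks taxonomic metagenome profiling results against a gold
    standard profile across the eight major taxonomic ranks (superkingdom to
    strain). Reads multi-sample profiles in the CAMI Bioboxes profiling format
    and in BIOM format, computes presence/absence metrics (purity,
    completeness, F1, Jaccard), abundance-aware metrics (L1 norm, Bray-Curtis,
    weighted and unweighted EMD UniFrac on the rank-restricted taxonomy tree),
    alpha and beta diversity summaries, rarefaction and accumulation curves,
    and ranks profilers by weighted per-metric scores. Results are written as
    tidy and per-rank/per-tool tables, static plots, and a self-contained HTML
    report. A synthetic profile generator with controlled perturbations
    (dropout, spurious taxa, abundance noise, rank truncation) supports
    testing and development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    biomformat,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    grDevices
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
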