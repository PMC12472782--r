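Package: prosieve
Title: Differential-Abundance Screening for Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible screening pipeline for label-free proteomic and
    phosphoproteomic abundance tables from factorial (genotype by treatment,
    optionally sex-stratified) designs. Provides k-nearest-neighbour outlier
    removal within experimental groups, four per-sample normalization schemes
    including down-scaling to the lowest sample total, fold-change computation
    with normality-routed two-group testing (Student's t or Mann-Whitney U
    after Shapiro-Wilk), asymmetric log2 fold-change volcano classification,
    relative-variance candidate ranking with top-fraction selection and
    Benjamini-Hochberg false-discovery-rate control, offline protein
    interaction subgraphing and hypergeometric term enrichment, an a-priori
    power computation for the two-way interaction contrast, and a synthetic
    spike-in data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
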