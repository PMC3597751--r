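Package: ecodomnet
Title: Domain Co-Occurrence Networks from Metagenomic Abundance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds protein-domain co-occurrence networks from metagenomic
    survey data. Parses HMMER3 per-domain tabular output, applies conservative
    hit-significance filters, cross-tabulates retained hits into a site-by-family
    abundance matrix, prunes and (optionally) standardizes it by site maxima,
    computes all-pairs Spearman rank correlations with Bonferroni control,
    assembles the thresholded association network, partitions it into clique-like
    transitivity clusters by weighted cluster editing (exact subset dynamic
    programming for small components, a time-budgeted heuristic for large ones),
    and reports category-bias statistics and taxonomic profiles for domains of
    unknown function. Includes a planted-module synthetic count-matrix generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
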