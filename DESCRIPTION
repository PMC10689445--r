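Package: auxoflux
Title: Amino Acid Auxotrophy Screening and Community Ecology from
    Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts amino-acid auxotrophies of bacterial genomes by
    flux-balance drop-out screens on genome-scale metabolic models, predicts
    growth-normalized fermentation by-products, and links auxotrophy
    frequencies in microbial communities to alpha diversity, longitudinal
    stability (1 - UniFrac) and host metabolite levels via Fisher exact,
    partial Spearman and Benjamini-Hochberg corrected association screens.
    Includes a synthetic-data generator (toy metabolic networks with planted
    auxotrophies, community abundance profiles, phylogenies, paired
    longitudinal samples and confounded metabolomes) so the whole pipeline is
    testable without external genome catalogs, and a bounded-variable simplex
    solver for the underlying linear programs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    ape,
    phangorn,
    vegan,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phyloseq
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
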