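Package: micromet
Title: Integrative Microbiome-Metabolome Correlation Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating 16S rRNA gene amplicon data with targeted
    metabolomics in multi-cohort case-control designs. Implements qPCR-based
    transformation of compositional counts to absolute (ecosystem) abundance,
    genus aggregation with prevalence filtering, centered log-ratio transforms
    and Aitchison-distance ordination with permutation tests (PERMANOVA and a
    dispersion test), alpha-diversity panels (Shannon, inverse Simpson, Chao1,
    Faith's phylogenetic diversity), rank-based univariate group comparisons
    with Benjamini-Hochberg correction, per-cohort taxon-metabolite Spearman
    association networks with FDR and magnitude filters, cross-cohort
    differential-network analyses (shared and unique edges, median-correlation
    sign flips, node rewiring), and hypergeometric over-representation
    analysis of metabolite sets. A Gaussian-copula simulator generates
    cohorts with planted genus-metabolite associations and a ground-truth
    table so that the whole pipeline can be exercised and calibrated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    picante,
    ape,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
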