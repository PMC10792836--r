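Package: admodnet
Title: Condition-Specific Disease Module Discovery and Network-Based Drug Prioritisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-data-testable pipeline for
    discovering a condition-specific disease module from paired
    (lesional / non-lesional) gene expression data and prioritising drugs by
    consensus disease similarity. Implements batch mean-adjustment, an
    ensemble of co-expression network inference algorithms (CLR, ARACNE,
    MRNET over seven correlation and mutual-information estimators) fused by
    Borda rank aggregation, a three-branch differential-expression
    meta-analysis (Fisher combined p-values, DerSimonian-Laird random-effects
    pooling of Hedges' g, rank product), network gene ranking (differential
    centrality, bridge genes), evidence-based seed selection, DIAMOnD
    connectivity-significance module expansion with differential selection
    between condition-specific networks, module characterisation
    (overrepresentation, Kolmogorov-Smirnov gene set enrichment, evidence-based
    edge ranking), and drug prioritisation via a hierarchical consensus of six
    disease-disease distance measures fused by Ipsen-Mikhailov spectral graph
    distances. Includes a synthetic data generator with planted differential
    co-expression modules and knowledge bases with controlled overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
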