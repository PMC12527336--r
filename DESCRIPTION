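Package: PhageMix
Title: Quantitative Phage Cocktail Design from Infection and Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs small phage cocktails from quantitative phage-bacteria
    infection networks (QPBIN) and optional quantitative phage-phage
    interaction networks (QPPIN). Effective virulence of each phage within a
    cocktail is modulated multiplicatively by pairwise interaction factors
    (values below 1 denote antagonism, above 1 synergy), and per-host growth
    inhibition combines phages by independent action (noisy-OR). Cocktails are
    found by exhaustive enumeration up to a size cap or by a resistance-weighted
    greedy heuristic, with multi-cocktail (rotation) series, network summary
    statistics (fill, binary entropy, host range, virulence, redundancy),
    structured text/TSV reports, Cytoscape-compatible SIF/GraphML export, and
    seeded synthetic network generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'matrix-io.R'
    'export-network.R'
    'network-metrics.R'
    'infection-model.R'
    'cocktail-search.R'
    'reporting.R'
    'synthetic-networks.R'
    'cli.R'
    'PhageMix-package.R'
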