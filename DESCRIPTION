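Package: phagedyn
Title: Diet-Driven Gut Virome Dynamics and Phage-Bacterium Interplay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for time-resolved diet-intervention virome
    studies. Implements length- and depth-normalized abundance, the
    subsampled Bray-Curtis community-convergence procedure, nomenclature
    based phage-host linking with a crAssphage override, three
    formulations of the lytic-lysogenic index (LLI) with Kruskal-Wallis /
    Dunn / Benjamini-Hochberg group comparisons, phage-bacterium Spearman
    correlation networks with interaction-strength change classification,
    per-project trend voting and phage-host concordance scoring,
    phage-mediated horizontal gene transfer classification, HGT-enzyme
    trajectory summaries, and the two-step auxiliary metabolic gene (AMG)
    reversal filter. A synthetic-study generator with recorded ground
    truth emulates a three-group mouse diet intervention so every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    yaml
Config/testthat/edition: 3
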