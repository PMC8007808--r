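Package: comodule
Title: Co-Expression Modules Jointly Associated with Two Disease Trait Groups
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds signed weighted gene co-expression networks from whole-blood
    expression matrices, detects modules by topological-overlap clustering with
    a static tree cut, summarises modules by eigengenes (first principal
    components), screens module-trait Pearson correlations with Bonferroni
    adjustment for modules related to early traits of two diseases
    (osteoporosis via pQCT bone traits, atherosclerosis via intima-media
    thickness), tests joint association with a bivariate trait outcome via
    Pillai's trace under three covariate-adjustment models, and performs
    hypergeometric over-representation of module genes against GMT gene-set
    collections with similarity-based clustering of enriched terms. Includes a
    synthetic-data generator with planted modules and known module-to-trait
    effects so every stage is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
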