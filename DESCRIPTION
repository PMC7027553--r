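Package: coldmeta
Title: Meta-Analysis of Warming Effects on Belowground Nitrogen in Cold
    Ecosystems
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to meta-analyze warmed-versus-control field experiments
    on belowground nitrogen pools, fluxes, enzymes, genes, and biota in
    cold ecosystems. Computes standardized mean difference effect sizes
    with their sampling variances, builds the shared-control
    variance-covariance matrix for effect sizes that reuse one control
    group, fits fixed-effect pooled estimates by generalized least
    squares, produces Wald and bias-corrected accelerated (BCa) bootstrap
    confidence intervals, runs subgroup analyses by soil depth, latitude
    band, and biome, and meta-regresses effect sizes on warming
    magnitude, experiment duration, and soil-moisture change with
    two-way interactions. Includes a synthetic study-table generator
    with known true effects for end-to-end validation, and a
    reproducible pipeline with CSV outputs and a JSON run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
Config/testthat/edition: 3
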