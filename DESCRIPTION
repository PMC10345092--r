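Package: phenoscreen
Title: Gene-Set Scoring and Phenotype Screens for Patch-Seq Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links gene-set expression in single human cortical neurons to
    cellular phenotypes measured in the same cells. Provides counts-per-million
    normalization and per-cell gene-set scoring of single-cell expression
    matrices, zero-prevalence gene filtering, donor-aware group comparisons
    (tie-corrected Kruskal-Wallis with Dunn-Holm post-hoc tests and Friedman
    tests on donor medians), per-gene phenotype correlation screens with
    Benjamini-Hochberg false discovery rate control and critical p-value
    reporting, gene-set overlap enrichment by one-sided Fisher tests,
    hypergeometric over-representation analysis with full or restricted
    backgrounds, action-potential rise-speed extraction from current-clamp
    sweeps, and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
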