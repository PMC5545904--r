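Package: crossbel
Title: Cross-Species Comparison of Cause-and-Effect Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds species-scoped causal graphs from a subset of the
    Biological Expression Language (BEL) or flat edge tables, matches
    human and mouse edges through gene-symbol orthology, and classifies
    every human interaction as consistent, contradictory or
    species-unique at the molecular and cellular levels. Also classifies
    per-gene cross-species differential-expression concordance from
    GEO2R-style call tables, runs hypergeometric over-representation
    analysis against GMT gene-set collections, and propagates drug
    perturbation signs through the graphs to compare predicted
    mode-of-action between species, as in the celecoxib
    neuroinflammation case study. Ships a synthetic-data generator that
    produces paired models and expression tables with known
    ground-truth category proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
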