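Package: traitorder
Title: Inference of Trait Emergence Order on Rooted Species Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps binary phenotypic traits onto a rooted species phylogeny
    under a single-origin (Dollo-style) assumption, assigns each trait an
    origin node, derives the pairwise and global order of trait emergence,
    quantifies homoplasy with per-trait consistency and retention indices,
    measures how often individual rooted gene trees reproduce the
    species-tree trait order, and classifies outgroup-rooted gene trees by
    which ingroup group is basal or ancestral. Ships a deterministic
    synthetic-data generator (Yule species trees, single-gain/multiple-loss
    traits, subsampled and NNI-perturbed gene trees) so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
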