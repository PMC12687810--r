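Package: lipidorigin
Title: Origin Classification and Perturbation Analysis of Intestinal Lipidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative lipidomics of gut contents: parsing of
    shorthand lipid nomenclature with acyl-chain parity classification,
    internal-standard normalization of feature-abundance matrices,
    classification of lipid origin (diet-derived, host-produced, or gut
    microbially-produced) by hierarchical clustering and by dual
    fold-difference plus Welch-test criteria, three-group
    perturbation/restoration categorization with volcano-style differential
    calls and Venn partitions, Bray-Curtis distances with (pairwise)
    PERMANOVA, and a synthetic-lipidome generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
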