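Package: nppm
Title: Nested Perfect Phylogeny Mixtures for Mitochondrial Lineage Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint inference of a mitochondrial clone tree and a concordant
    cell lineage tree from per-cell mitochondrial variant allele frequencies.
    Implements the nested perfect phylogeny mixture model: the observed
    cell-by-mutation frequency matrix F is factorized as F = U B where U is a
    cell-by-clone mixture matrix, B is a perfect phylogeny clone matrix, and
    the clone tree is required to be concordant with the cell lineage tree
    encoded by the support pattern of U. Provides an exact mixed-integer
    linear programming solver minimizing the L1 reconstruction error, the
    combinatorial feasibility theory (ancestry graphs, spanning arborescence
    enumeration, sum and strictness conditions), a concordant-instance
    simulator with beta-binomial read counts, and clone-tree accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
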