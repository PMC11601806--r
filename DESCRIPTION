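Package: sdagsearch
Title: Systematic Search for High Posterior Density Phylogenies with Subsplit DAGs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data structures and algorithms for representing collections of rooted
    bifurcating phylogenetic topologies as a subsplit directed acyclic graph (sDAG),
    and for systematically enlarging an sDAG via nearest-neighbor-interchange (NNI)
    operations so that it covers a high posterior density region of tree space.
    Implements the subsplit algebra, sDAG construction/completion/enumeration,
    Jukes-Cantor likelihood with Felsenstein pruning and Brent branch-length
    optimization, two NNI ranking criteria (the top-pruning likelihood via choice
    maps and best known trees, and the generalized-pruning per-edge topology-marginal
    composite likelihood), probability distributions on sDAG topologies, and
    posterior-coverage evaluation against empirical topology posteriors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
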