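Package: l1net
Title: Combinatorics of Binary Level-1 Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the combinatorial analysis of rooted binary level-1
    (galled) phylogenetic networks: validation and structural queries (galls,
    cut arcs, the Cut partition, Collapse, restriction, displayed trees),
    induced rooted-triplet and softwired-cluster systems with two independent
    extraction algorithms, SN-set decompositions, explicit constructions of
    small triplet and cluster systems that uniquely determine a simple network
    within the class of all level-1 networks on the same taxa, exhaustive and
    random generators for small leaf sets, and verification drivers that check
    the counting formulas and uniqueness results computationally.  Networks are
    read and written as extended Newick (with #H hybrid tags) or a JSON edge
    list; triplet and cluster systems as TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    withr
Config/testthat/edition: 3
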