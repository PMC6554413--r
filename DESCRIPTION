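Package: ndseq
Title: Neighbourhood Degree Sequence Indices for Complex Networks
Version: 0.1.0
Authors@R: person("ndseq", "developers", email = "ndseq@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the neighbourhood degree sequences of
    undirected networks. Implements node heterogeneity, relative node
    heterogeneity, neighbourhood similarity, the neighbourhood organisation
    coefficient, and hierarchical complexity with its multi-order correction,
    together with the height-2 Weisfeiler-Lehman subtree signature, classical
    global network indices (transitivity, degree variance, characteristic path
    length, assortativity, modularity), configuration-model null ensembles by
    degree-preserving edge rewiring, random-graph generators, Spearman
    correlation matrices, paired Wilcoxon tests with rank-biserial effect
    sizes, and file readers/writers for edge lists, Matrix Market adjacency,
    GraphML and dense adjacency CSV, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
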