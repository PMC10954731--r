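Package: ncfchain
Title: Chain Functions Within Nested Canalyzing Logic for Boolean Gene
    Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying, counting and sampling chain-0, chain-1
    and generalized chain functions within the nested canalyzing functions
    (NCFs) that dominate reconstructed Boolean models of gene regulation.
    Provides exact closed-form and enumeration-based counts of the function
    classes, the bias-wise fraction of chain functions among NCFs and its
    limiting constant, relative-enrichment statistics with binomial
    p-values for collections of regulatory logic rules, synchronous Boolean
    network dynamics with attractor and basin analysis, mean-first-passage-
    time estimates of relative cell-state stability under noisy dynamics,
    and selection of network models constrained by fixed points,
    interaction signs, function classes and stability hierarchies.
    Includes readers for BoolNet-style model files and tabular function
    collections, plus synthetic generators for planted-class datasets and
    random signed networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
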