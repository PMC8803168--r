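Package: elsplice
Title: Enhancer lncRNA Splicing, Selective Constraint, and Cis-Regulatory
    Causality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links the splicing of enhancer-associated long noncoding RNAs
    (elncRNAs) to the activity of their cognate enhancers. Implements
    intron-centric splicing quantification (percent-spliced-in from
    LeafCutter-style intron clusters, completed splicing index),
    splice-motif evolutionary-constraint testing against GC- and
    length-matched local ancestral repeats, derived-allele-frequency
    spectrum comparison, permutation-calibrated cis-QTL mapping within
    topologically associating domains, joint splicing/expression QTL
    triplet construction, and a four-model (causal, reactive, independent,
    undecided) mediation classifier with an empirical-null local false
    discovery rate. A synthetic-cohort generator with planted effects
    makes the whole inference chain testable without population-scale
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
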