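Package: polarniche
Title: Ecological Niche Statistics and Polar-Adaptation Inference for
    Ocean Giant Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to infer polar adaptation of marine giant viruses from
    metagenomic abundance profiles. Implements robust ecological optimum
    and tolerance estimation from abundance-weighted environmental
    vectors, Polar/Nonpolar niche classification with zero-signal rules
    and rank-sum tests, community diversity and ANOSIM statistics,
    equal-rates Markov ancestral niche reconstruction with transition
    counting and relative evolutionary divergence, Pagel's lambda
    phylogenetic-signal tests, Faith's phylogenetic diversity,
    co-occurrence based virus-host prediction by clade enrichment, and
    polar gene/pathway enrichment analyses. A synthetic-data generator
    with known ground truth emulates the structure of global ocean
    survey data so the whole pipeline can be exercised and validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phytools,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
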