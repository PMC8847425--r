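Package: markpatterns
Title: Dynamic Histone-Mark Pattern Analysis Across Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls per-gene and per-peak Increased/Unchanged states of a
    histone modification (e.g. H3K27me3, H3K27ac) against Input chromatin
    from binned coverage tracks, classifies units into cross-genotype
    dynamic patterns over a reference/disease/rescue design (GP1-GP4 and
    PP1-PP4), applies a peak-level fold-change consistency filter, and
    tests gene sets for pattern enrichment with a binomial survival test
    whose background is learned genome-wide. Includes a negative-binomial
    synthetic ChIP/Input coverage simulator with planted pattern truth for
    end-to-end validation, readers and writers for bedGraph, BED, minimal
    GTF, GMT and chrom.sizes, and a config-driven pipeline with a thin
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
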