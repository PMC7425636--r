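Package: hiccf
Title: Cumulative Contact Frequency Analysis of Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the cumulative contact frequency (CCF) of genomic bins
    from raw (non-normalized) Hi-C contact matrices and relates it to genome
    function. Provides A/B compartment calling by PCA of the
    observed-over-expected correlation matrix, modularity-based TAD
    segmentation by dynamic programming, per-bin chromatin-state coverage
    with active/inactive groupings, genome-wide and windowed correlation
    analyses with permutation and downsampling controls, projection of CCF
    between genomes through synteny block maps, and a synthetic Hi-C
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
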