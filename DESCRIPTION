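Package: numtscan
Title: Numt Detection and Heteroplasmy Calling from Cloned Mitochondrial
    Control-Region Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting intra-individual variation in cloned
    mitochondrial control-region sequences. Decomposes the R2 tandem-repeat
    array of the CSB domain into run-length motif structures, computes Kimura
    2-parameter distances and net between-group divergences on repeat-masked
    alignments, partitions clone sequences into clades and builds minimum
    spanning haplotype networks, distinguishes nuclear mitochondrial
    pseudogenes (numts) from authentic mtDNA by repeat content, anchor
    sequences and mutational-step density, calls sequence and length
    heteroplasmy per individual with a Poisson polymerase-error model, and
    simulates clone data sets with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
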