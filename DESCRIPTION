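Package: optipool
Title: Decoding and Kinetic Analysis of Pooled Optical Screens in the Mother Machine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computational pipeline for pooled optical screens of chromosomally
    barcoded Escherichia coli strains in mother-machine microfluidics: design and
    filtering of DNA barcodes and padlock-probe hybridisation arms, construction of
    error-correcting colour codebooks, in situ genotype decoding with single-error
    correction and error-rate estimation, lineage-level fluorescence phenotyping,
    fluorescent-protein maturation-time fitting with single- and double-exponential
    models, and density-based phenotype outlier detection. A seeded synthetic-data
    generator emulates the genotyping signals, lineage traces and amplicon reads the
    pipeline consumes, with full ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    tiff,
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
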