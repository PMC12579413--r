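Package: polledtrio
Title: Trio-Based Structural Forensics of the Bovine POLLED Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of sire-dam-offspring trios segregating
    the dominant polled (hornless) variants of bovine chromosome 1
    (2.42-2.73 Mb): sequence-level models of the Celtic, Friesian, Mongolian
    and Guarani alleles, allelic and non-allelic homologous recombination
    products across the 80,128-bp Friesian tandem duplication, long-read
    simulation with truth-projected split alignments, split-read breakpoint
    clustering, windowed read-depth scanning, trio Mendelian checks and
    recombination-breakpoint localization from SNP panels, an in-silico
    analog of the diagnostic polled genotyping test, and a rule engine that
    classifies the evidence into the competing structural hypotheses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
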