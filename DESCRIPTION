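Package: satprobe
Title: Selection of Chromosome-Specific Satellite DNA Targets for FISH Probes
Version: 0.1.0
Authors@R: person("satprobe", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An in-silico workflow for designing chromosome enumeration
    FISH probes that target satellite DNA. Scans repeat annotations for
    regions densely covered by tandem satellite repeats but free of
    interspersed (non chromosome-specific) elements, selects BAC clones
    contained in such regions, designs repeat-targeting PCR primers that
    avoid a satellite consensus motif, predicts amplicons by in-silico
    PCR, and profiles candidate probe sequences for cross-chromosome
    specificity with a deterministic k-mer screen. Ships a seeded
    synthetic-genome generator with planted repeat arrays and a truth
    manifest so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
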