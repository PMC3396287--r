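Package: tilepeaks
Title: Analysis of Two-Colour Promoter Tiling-Array ChIP-chip Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Data preparation and analysis for chromatin immunoprecipitation
    experiments hybridised to two-colour promoter tiling microarrays, geared
    towards miniaturised assays on rare cell populations. Implements MA
    transformation and within-array dye-bias correction, quantile
    normalization restricted to replicate arrays, replicate averaging,
    sliding-window peak detection with a cutoff ramp and permutation-based
    false discovery rates, unique peak-to-promoter assignment within
    strand-oriented TSS windows, present/absent promoter calls, a signed
    net-enrichment statistic combining activating and silencing histone
    marks, integration with gene expression, percent-input quantification of
    ChIP-qPCR data, and a quality-control battery. A seeded synthetic-data
    generator emulates the probe-level structure of two-colour tiling arrays
    (dye bias, between-array scale shifts, replicate noise, mark-specific
    spatial enrichment profiles) so that the whole pipeline is testable
    without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    limma,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
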