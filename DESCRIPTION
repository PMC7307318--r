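Package: methmapr
Title: Map Differential DNA Methylation Array Tables onto Genomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Takes probe-level differential DNA-methylation tables from
    Illumina 450K/EPIC array pipelines (RnBeads or ChAMP exports, or a simple
    custom schema), maps the probes onto user-named genomic features (gene
    promoters, gene bodies, whole genes, or RepeatMasker repeat classes), and
    produces per-feature summary statistics on a 1-1000 methylation scale
    together with UCSC-ready bedGraph tracks (absolute methylation, delta,
    and FDR-filtered significance tracks). Includes a seeded synthetic-data
    generator so the whole pipeline can be exercised and validated without
    any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
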