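Package: stallscan
Title: Ribosome Profiling Analysis of Translation Arrest at Polybasic Tracts
Version: 0.1.0
Authors@R:
    person("stallscan", "developers", email = "stallscan@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying ribosome stalling at polybasic-encoding
    tracts from ribosome profiling data. Discovers tract windows (>= k basic
    residues in a 10-residue window) in coding sequences, builds read-frequency
    metaprofiles around tract centers, computes post-/pre-tract occupancy
    ratios with transcript-level filters and matched-control resampling, and
    derives reporter-specific read-through metrics. Also implements
    side-scatter-normalized flow-cytometry reporter ratios with ANOVA/Tukey
    group statistics and a pseudocount spectral-count enrichment score for
    IP mass spectrometry. A seeded synthetic-data module generates every
    input the pipeline consumes (CDS FASTA, footprint BED, coverage tables,
    flow event tables, spectral-count tables) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
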