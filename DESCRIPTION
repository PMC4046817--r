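Package: ChIPtiling
Title: Replicate-Consistent ChIP-Chip Peak Calling and Binding-Energy Motif
    Scanning for Small Circular Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing transcription-factor occupancy measured on
    tiling microarrays of small (typically archaeal or bacterial) circular
    genomes. Implements running-median smoothing and threshold-based calling
    of enriched regions with a replicate-consistency and mock-ChIP filter,
    binding-energy position weight matrix scanning with theoretical
    dissociation constants, genomic-context annotation of enriched regions,
    two-factor co-occupancy classification, and the accompanying wet-lab
    quantitation: ChIP-qPCR enrichment ratios, equilibrium binding isotherm
    fitting, and 2^-ddCt relative expression with significance testing.
    Ships a synthetic-data generator that emulates the full study design
    (planted binding sites of graded affinity, fragment-smeared probe
    signal, replicate and mock noise, titration and Cq tables) so every
    stage can be validated against planted truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
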