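Package: telocrisis
Title: Telomere Fusion Amplicon Analysis Through Replicative Crisis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Resolves telomere-fusion amplicon sequencing reads into
    classified junction calls with microhomology, templated-insertion and
    subtelomeric-deletion metrics; generates matched simulated-fusion null
    sets resolved by the identical methodology; computes per-chromosome and
    per-feature enrichment statistics for fusion junctions; calls
    single-nucleus copy-number alterations from binned read counts
    normalised to a pooled-nuclei baseline and intersects them with fusion
    loci; and links fused genes to stage-labelled expression data. A
    synthetic-data layer simulates subtelomere references, fusion amplicons
    with known junction structure, 4N-nucleus bin counts and stage-structured
    count matrices, so every analysis step is testable against recorded
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
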