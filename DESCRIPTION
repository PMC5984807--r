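Package: mpsa
Title: Design and Quantification of Barcoded Minigene Splicing Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for massively parallel splicing reporter assays that measure
    how genetic variants change exon inclusion. Designs barcoded test-exon
    oligo pools from exon annotations, a genome, and variant calls; verifies
    barcode-variant associations from plasmid amplicon sequencing (per-barcode
    fidelity filtering, misassignment rate, library skew); quantifies percent
    spliced in (PSI) and variant effects (delta PSI) from UMI-tagged RNA
    amplicon reads via anchored splice-junction classification; and runs
    downstream analyses including exonic splicing enhancer hexamer score
    deltas, cross-condition directionality agreement, premature termination
    codon prediction with a nonsense-mediated decay regression model, and
    conservation contrasts. A simulator generates read sets with known ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
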