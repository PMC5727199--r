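Package: tubahdr
Title: Tumor Barcode Sequencing Analysis for Multiplexed Kras Variant
    Oncogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multiplexed tumor-barcode amplicon sequencing from
    pools of Kras variants engineered by somatic homology-directed repair.
    Turns bulk-tissue amplicon reads into called tumors with absolute
    neoplastic cell numbers: read merging and trimming, residual error-rate
    estimation from invariant flanks, abundance p-value denoising of read
    pileups, shadow-call removal, spike-in normalization, a multinomial
    barcode-collision model with a Brent solve for the true tumor number,
    and per-variant oncogenicity statistics (library-representation
    normalization, exact tests against reference alleles, bootstrap
    confidence intervals). Includes a synthetic-data generator with ground
    truth for parameter-recovery testing, clonal lineage mapping across
    multi-region and metastasis samples via shared variant-barcode pairs,
    and trinucleotide mutational-signature normalization of observed
    mutation spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
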