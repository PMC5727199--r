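# shared fixtures built in code

uniform_codon_table <- function() {
  nts <- c("A", "C", "G", "T")
  codons <- sort(as.vector(outer(as.vector(outer(nts, nts, paste0)), nts,
                                 paste0)))
  tibble::tibble(codon = codons, frequency = rep(1 / 64, 64))
}

fixture_codon_table <- function() {
  read_codon_usage(system.file("extdata", "synthetic_mouse_codon_usage.tsv",
                               package = "tubahdr"))
}

fixture_signature_table <- function() {
  read_signature_table(system.file("extdata", "synthetic_signatures.tsv",
                                   package = "tubahdr"))
}

# frequency model with exactly uniform per-position frequencies
uniform_freq_model <- function(design = kras_design()) {
  pool <- tibble::tibble(variant = "WT",
                         barcode = enumerate_barcodes(design), reads = 1L)
  fit_barcode_frequencies(pool, design)
}

# random valid (variant, barcode) pairs under the default design
random_alleles <- function(n, design = kras_design(), include_wt = TRUE) {
  classes <- allele_classes(design)
  if (!include_wt) classes <- classes[classes$variant != "WT", ]
  bc <- vapply(seq_len(n), function(i) {
    paste(vapply(design$wobble_alphabets, function(a) sample(a, 1L), ""),
          collapse = "")
  }, character(1))
  tibble::tibble(variant = sample(classes$variant, n, replace = TRUE),
                 barcode = bc)
}

# mouse Kras exon-2 context around codons 12/13 (codons 1-22), for
# signature-context tests
kras_cds_fragment <- function() {
  paste0("ATGACTGAGTATAAACTTGTGGTAGTTGGAGCT", "GGTGGC",
         "GTAGGCAAGAGTGCCTTGACGATACAG")
}
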