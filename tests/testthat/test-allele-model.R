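test_that("variant enumeration yields the 12 non-synonymous substitutions", {
  v <- enumerate_variants("GGT", "GGC")
  expect_equal(nrow(v), 12L)
  expect_setequal(
    v$variant,
    c("G12A", "G12C", "G12D", "G12R", "G12S", "G12V",
      "G13A", "G13C", "G13D", "G13R", "G13S", "G13V")
  )
  # independent oracle: translate all 18 single-nt substitutions of each
  # codon with the standard genetic code and keep the non-synonymous ones
  oracle <- function(codon) {
    bases <- strsplit(codon, "")[[1]]
    out <- character(0)
    for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), bases[pos])) {
      mut <- bases; mut[pos] <- nt
      mut <- paste(mut, collapse = "")
      if (Biostrings::GENETIC_CODE[[mut]] != Biostrings::GENETIC_CODE[[codon]])
        out <- c(out, mut)
    }
    out
  }
  expect_setequal(v$codon12[v$residue == 12], oracle("GGT"))
  expect_setequal(v$codon13[v$residue == 13], oracle("GGC"))
  # G12D is realized as GAT (G>A at the middle base of GGT)
  expect_equal(v$codon12[v$variant == "G12D"], "GAT")
  # third-position substitutions of GGT are synonymous and absent
  expect_false(any(v$codon12 %in% c("GGA", "GGC", "GGG")))
  # with WT the library has 13 allele classes
  expect_equal(nrow(allele_classes()), 13L)
  expect_error(enumerate_variants("GGX", "GGC"), "DNA")
})

test_that("barcode space size follows the wobble alphabets", {
  d <- kras_design()
  expect_equal(n_barcodes(d), 24576L)
  expect_equal(free_parameters(d), 21L)

  all4 <- kras_design(wobble_alphabets = rep(list(c("A", "C", "G", "T")), 8))
  expect_equal(n_barcodes(all4), 4^8)
  one_fixed <- kras_design(wobble_alphabets = c(
    list("A"), rep(list(c("A", "C", "G", "T")), 7)))
  expect_equal(n_barcodes(one_fixed), 4^7)

  # enumeration agrees with the count and is unique and lexicographic
  small <- kras_design(wobble_alphabets = c(
    rep(list(c("A", "T")), 6), list(c("C", "G")), list("A")))
  bcs <- enumerate_barcodes(small)
  expect_equal(length(bcs), n_barcodes(small))
  expect_false(anyDuplicated(bcs) > 0)
  expect_equal(bcs, sort(bcs))

  bcs_default <- enumerate_barcodes(d)
  expect_equal(length(bcs_default), 24576L)
  expect_false(anyDuplicated(bcs_default) > 0)
})

test_that("parsing inverts synthesis for random alleles", {
  set.seed(41)
  alleles <- random_alleles(200)
  cores <- synthesize_core(alleles$variant, alleles$barcode)
  expect_true(all(nchar(cores) == 60L))
  parsed <- parse_reads(cores)
  expect_true(all(parsed$status == "ok"))
  expect_equal(parsed$variant, alleles$variant)
  expect_equal(parsed$barcode, alleles$barcode)
})

test_that("parsing rejects malformed reads with reason codes", {
  core <- synthesize_core("G12D", "AGGGGTGC")
  # anchor/invariant mismatch (first prefix base)
  bad_anchor <- paste0("A", substr(core, 2, 60))
  expect_equal(parse_reads(bad_anchor)$reason, "anchor_mismatch")
  # unknown codon pair (synonymous codon-12 change is not a library allele)
  d <- kras_design()
  bad_codon <- core
  substr(bad_codon, 17, 19) <- "GGA"
  expect_equal(parse_reads(bad_codon)$reason, "unknown_codon")
  # barcode base outside its alphabet (wobble position 3 allows only A/G)
  rg_start <- 25L  # region start within the core
  bad_bc <- core
  substr(bad_bc, rg_start + 6L, rg_start + 6L) <- "C"
  expect_equal(parse_reads(bad_bc)$reason, "bad_barcode_base")
  # wrong length
  expect_equal(parse_reads(substr(core, 1, 59))$reason, "bad_length")
  expect_equal(parse_reads(c(core, bad_anchor))$status, c("ok", "rejected"))
})

test_that("the documented spike-in parses to G12V with its barcode", {
  sp <- spikein_allele()
  parsed <- parse_reads(synthesize_core(sp$variant, sp$barcode))
  expect_equal(parsed$variant, "G12V")
  expect_equal(parsed$barcode, "CGGGGTGC")
  # its codon 12 is GTT (G>T at the middle base)
  expect_equal(substr(parsed$seq, 17, 19), "GTT")
})

test_that("codon usage score sums the 8 codons overlapping the region", {
  uni <- uniform_codon_table()
  expect_equal(codon_usage_score("CGGGGTGC", uni), 8 / 64)
  expect_equal(codon_usage_score(NULL, uni, reference = "wt"), 8 / 64)

  # additivity: alleles differing at one wobble base differ by exactly the
  # table difference of the two affected codons
  tbl <- fixture_codon_table()
  s1 <- codon_usage_score("AGGGGTGC", tbl)
  s2 <- codon_usage_score("CGGGGTGC", tbl)
  f <- function(codon) tbl$frequency[tbl$codon == codon]
  expect_equal(s2 - s1, f("GTC") - f("GTA"))

  # reference scores against a hand-summed oracle on the fixture table
  wt_codons <- c("GTA", "GGC", "AAG", "AGT", "GCC", "TTG", "ACG", "ATA")
  minimal_codons <- c("GTA", "GGC", "AAG", "TCT", "GCC", "CTG", "ACG", "ATA")
  expect_equal(codon_usage_score(NULL, tbl, reference = "wt"),
               sum(vapply(wt_codons, f, 1)))
  expect_equal(codon_usage_score(NULL, tbl, reference = "minimal"),
               sum(vapply(minimal_codons, f, 1)))
})

test_that("codon usage log2 fold change is relative to 1/64", {
  tbl <- uniform_codon_table()
  tbl$frequency[1] <- 1 / 32
  tbl$frequency[2] <- 1 / 128
  tbl$frequency[3] <- 0
  out <- codon_usage_log2fc(tbl)
  expect_equal(out$log2fc[1], 1)
  expect_equal(out$log2fc[2], -1)
  expect_equal(out$log2fc[3], -Inf)
  expect_equal(out$log2fc[4], 0)
})

test_that("pairwise identity counts matching aligned positions", {
  set.seed(7)
  aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 188,
                     replace = TRUE), collapse = "")
  expect_equal(pairwise_identity(aa, aa),
               tibble::tibble(matches = 188L, length = 188L, percent = 100))
  # mutate 5 positions: 183/188 = 97%
  b <- strsplit(aa, "")[[1]]
  pos <- sample(188, 5)
  b[pos] <- vapply(b[pos], function(x) setdiff(c("A", "W", "K"), x)[1], "")
  res <- pairwise_identity(aa, paste(b, collapse = ""))
  expect_equal(res$matches, 183L)
  expect_equal(res$percent, 97)
  expect_error(pairwise_identity(aa, substr(aa, 1, 100)), "equal length")
})
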