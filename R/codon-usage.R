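#' Read a codon-usage table
#'
#' Reads the standard 2-column TSV format (codon, frequency). Frequencies are
#' usage fractions (unitless); the table must contain all 64 codons.
#'
#' @param path Path to a tab-separated file with columns `codon`, `frequency`.
#' @return A tibble with columns `codon`, `frequency`.
#' @export
read_codon_usage <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    codon = readr::col_character(), frequency = readr::col_double()
  ))
  validate_codon_usage(tbl)
}

validate_codon_usage <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("codon", "frequency") %in% names(tbl)))
  tbl$codon <- toupper(tbl$codon)
  if (nrow(tbl) != 64L || anyDuplicated(tbl$codon) ||
      !all(grepl("^[ACGT]{3}$", tbl$codon))) {
    stop("codon-usage table must have exactly the 64 DNA codons", call. = FALSE)
  }
  if (any(tbl$frequency < 0)) stop("codon frequencies must be >= 0", call. = FALSE)
  tbl
}

codon_lookup <- function(codons, table) {
  idx <- match(codons, table$codon)
  if (anyNA(idx)) {
    stop("codon(s) absent from usage table: ",
         paste(unique(codons[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  table$frequency[idx]
}

# In-frame codons overlapping the 22-nt barcode region: spacer (codon 14
# bases 1-2) + region = 24 nt = codons 14..21.
region_codons <- function(region_seq, design) {
  frame <- paste0(design$spacer, region_seq)
  starts <- seq(1L, nchar(frame) - 2L, by = 3L)
  substring(frame, starts, starts + 2L)
}

#' Codon-usage score of the barcoded region
#'
#' Sum of codon-usage frequencies over every codon with at least one base in
#' the 22-nt barcode region (codons 14-21 of the allele; the region is not
#' codon-aligned, so codon 14 enters through its third base). `reference`
#' selects the realized allele for a barcode, the wild-type region, or the
#' "minimal" allele carrying the three anchors but wild-type wobble bases.
#'
#' @param barcode Character vector of 8-character barcodes (ignored for the
#'   reference scores).
#' @param table Codon-usage tibble from [read_codon_usage()].
#' @param design A [kras_design()].
#' @param reference One of "allele" (default), "wt", "minimal".
#' @return Numeric vector of scores (unitless sums of usage fractions).
#' @examples
#' tbl <- tibble::tibble(codon = names(Biostrings::GENETIC_CODE),
#'                       frequency = rep(1 / 64, 64))
#' codon_usage_score("CGGGGTGC", tbl)  # 8/64 under a uniform table
#' @export
codon_usage_score <- function(barcode = NULL, table, design = kras_design(),
                              reference = c("allele", "wt", "minimal")) {
  reference <- match.arg(reference)
  table <- validate_codon_usage(table)
  region <- switch(reference,
    allele = {
      stopifnot(!is.null(barcode))
      barcode_region(barcode, design)
    },
    wt = design$wt_region,
    minimal = {
      # anchors applied to the wild-type region, wobble bases left wild-type
      wt <- strsplit(design$wt_region, "")[[1]]
      tmpl <- strsplit(design$region_template, "")[[1]]
      wt[design$anchor_pos] <- tmpl[design$anchor_pos]
      paste(wt, collapse = "")
    }
  )
  vapply(region, function(r) sum(codon_lookup(region_codons(r, design), table)),
         numeric(1), USE.NAMES = FALSE)
}

#' Per-codon log2 fold change of usage relative to uniform (1/64)
#'
#' @param table Codon-usage tibble from [read_codon_usage()].
#' @return The table with an added `log2fc` column; codons with zero
#'   frequency get `-Inf` (no pseudo-counts are applied).
#' @export
codon_usage_log2fc <- function(table) {
  table <- validate_codon_usage(table)
  table$log2fc <- ifelse(table$frequency > 0,
                         log2(table$frequency * 64), -Inf)
  table
}

#' Position-wise identity of two aligned protein sequences
#'
#' Gap-free positional comparison of two equal-length amino-acid strings
#' (e.g. the 188-residue mouse and human KRAS orthologs).
#'
#' @param seq_a,seq_b Equal-length protein strings.
#' @return A tibble with `matches`, `length`, `percent` (rounded to integer).
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must have equal length (gap-free positional comparison)",
         call. = FALSE)
  }
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  matches <- sum(a == b)
  tibble::tibble(
    matches = matches,
    length = length(a),
    percent = round(100 * matches / length(a))
  )
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a named
#' character vector, for feeding [pairwise_identity()].
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
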