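#' Pyrimidine-centric 96-class label of a point substitution
#'
#' Labels a substitution by its trinucleotide context (the substituted base
#' plus its 5' and 3' neighbors) in the standard pyrimidine-strand
#' convention: when the reference base is a purine, substitution and context
#' are reverse-complemented before labeling, so complementary descriptions
#' of the same event map to the same class.
#'
#' @param cds DNA string (coding sequence or any strand context).
#' @param position 1-based index of the substituted base (must have both
#'   neighbors).
#' @param alt Alternate nucleotide (must differ from the reference).
#' @return Character label like `"T[C>T]A"` (vectorized over
#'   `position`/`alt`).
#' @export
mutation_context <- function(cds, position, alt) {
  stopifnot(length(cds) == 1L, grepl("^[ACGT]+$", cds))
  n <- max(length(position), length(alt))
  position <- rep_len(position, n)
  alt <- rep_len(alt, n)
  if (any(position < 2L | position > nchar(cds) - 1L)) {
    stop("position must have both neighbors inside the sequence",
         call. = FALSE)
  }
  ref <- substr(rep(cds, n), position, position)
  if (any(ref == alt)) stop("alt must differ from the reference base",
                            call. = FALSE)
  up <- substr(rep(cds, n), position - 1L, position - 1L)
  down <- substr(rep(cds, n), position + 1L, position + 1L)

  flip <- ref %in% c("A", "G")
  comp <- function(x) chartr("ACGT", "TGCA", x)
  lab_up <- ifelse(flip, comp(down), up)
  lab_down <- ifelse(flip, comp(up), down)
  lab_ref <- ifelse(flip, comp(ref), ref)
  lab_alt <- ifelse(flip, comp(alt), alt)
  paste0(lab_up, "[", lab_ref, ">", lab_alt, "]", lab_down)
}

#' All 96 trinucleotide substitution classes
#'
#' @return Character vector of the 96 pyrimidine-centric class labels.
#' @export
signature_classes <- function() {
  nts <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (u in nts) for (d in nts) {
      out <- c(out, paste0(u, "[", s, "]", d))
    }
  }
  out
}

#' Read a mutational-signature probability table
#'
#' Standard long-format TSV with a `class` column (96 pyrimidine-centric
#' labels like `T[C>T]A`) and one numeric column per named signature. Each
#' signature column must cover the 96 classes with non-negative
#' probabilities.
#'
#' @param path TSV path.
#' @return Tibble with `class` plus one column per signature.
#' @export
read_signature_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    class = readr::col_character(), .default = readr::col_double()
  ))
  validate_signature_table(tbl)
}

validate_signature_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot("class" %in% names(tbl))
  if (!setequal(tbl$class, signature_classes()) || nrow(tbl) != 96L) {
    stop("signature table must have exactly the 96 trinucleotide classes",
         call. = FALSE)
  }
  sig_cols <- setdiff(names(tbl), "class")
  if (length(sig_cols) == 0L) stop("no signature columns", call. = FALSE)
  for (s in sig_cols) {
    if (any(tbl[[s]] < 0)) stop("negative probability in ", s, call. = FALSE)
  }
  tbl
}

#' Enumerate the non-synonymous single-nucleotide mutations of two codons
#'
#' Applies the variant enumeration to codons at `codon_positions` of a CDS
#' and returns, for each non-synonymous substitution, the CDS position, the
#' reference/alternate bases and the 96-class context label.
#'
#' @param cds Coding DNA string containing the codons and their neighbors.
#' @param codon_positions Integer codon indices (default `c(12, 13)`).
#' @return Tibble `variant`, `cds_position`, `ref`, `alt`, `class`.
#' @export
codon_mutation_contexts <- function(cds, codon_positions = c(12L, 13L)) {
  out <- list()
  for (cp in codon_positions) {
    start <- 3L * (cp - 1L) + 1L
    codon <- substr(cds, start, start + 2L)
    aa_wt <- translate_codon(codon)
    bases <- strsplit(codon, "")[[1]]
    for (k in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), bases[k])) {
        mut <- bases
        mut[k] <- alt
        aa <- translate_codon(paste(mut, collapse = ""))
        if (aa == aa_wt) next
        pos <- start + k - 1L
        out[[length(out) + 1L]] <- tibble::tibble(
          variant = paste0(aa_wt, cp, aa),
          cds_position = pos, ref = bases[k], alt = alt,
          class = mutation_context(cds, pos, alt)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Relative induction frequencies of codon 12/13 mutations
#'
#' For each of the 12 non-synonymous single-nucleotide mutations at the two
#' codons, sums the probabilities of the included signatures for the
#' mutation's trinucleotide class, then normalizes within the 12 mutations
#' so the output sums to 1. Intended for tumor-extrinsic signatures (e.g.
#' smoking-related plus clock-like) to approximate how often each mutation
#' is induced in the cells of origin.
#'
#' @param cds Coding DNA string (human KRAS context by default use case).
#' @param table Signature tibble from [read_signature_table()].
#' @param signatures Character names of signature columns to include.
#' @param codon_positions Codon indices (default `c(12, 13)`).
#' @return Tibble `variant`, `class`, `probability` (summed), `induction`
#'   (normalized; sums to 1).
#' @export
relative_induction <- function(cds, table,
                               signatures = setdiff(names(table), "class"),
                               codon_positions = c(12L, 13L)) {
  table <- validate_signature_table(table)
  stopifnot(all(signatures %in% names(table)))
  muts <- codon_mutation_contexts(cds, codon_positions)
  idx <- match(muts$class, table$class)
  if (anyNA(idx)) stop("context class missing from table", call. = FALSE)
  prob <- rowSums(as.matrix(table[idx, signatures, drop = FALSE]))
  total <- sum(prob)
  if (total == 0) stop("all included signature probabilities are zero",
                       call. = FALSE)
  tibble::tibble(variant = muts$variant, class = muts$class,
                 probability = prob, induction = prob / total)
}

#' Normalize observed mutation prevalence by induction frequency
#'
#' Divides observed per-mutation counts by their relative induction
#' frequencies and renormalizes, yielding the mutation-rate-adjusted
#' relative prevalence (how enriched each mutation is beyond how often it is
#' generated).
#'
#' @param counts Tibble `variant`, `n` of observed mutation counts.
#' @param induction Tibble from [relative_induction()] (`variant`,
#'   `induction`).
#' @return Tibble `variant`, `n`, `induction`, `adjusted` (sums to 1).
#' @export
normalize_prevalence <- function(counts, induction) {
  out <- dplyr::left_join(counts, induction[, c("variant", "induction")],
                          by = "variant")
  bad <- is.na(out$induction) | (out$induction == 0 & out$n > 0)
  if (any(bad)) {
    stop("zero or missing induction frequency for observed mutation(s): ",
         paste(out$variant[bad], collapse = ", "), call. = FALSE)
  }
  raw <- ifelse(out$n > 0, out$n / out$induction, 0)
  out$adjusted <- if (sum(raw) > 0) raw / sum(raw) else raw
  out
}
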