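#' Amplicon and barcode design for the Kras HDR allele
#'
#' Describes the 60-nt amplicon core that carries a Kras codon 12/13 variant
#' and its clone-identifying barcode. The barcode occupies the 22-nt stretch
#' from the third base of codon 14 to the third base of codon 21: the eight
#' "wobble" (third-codon, synonymous) positions are randomized during library
#' synthesis while the intervening first/second codon bases stay fixed. Three
#' of the fixed bases are anchors that differ from wild-type Kras (they
#' synonymously recode Ser17 AGT to TCN and Leu19 TTG to CTN) so that every
#' engineered allele is distinguishable from the wild-type locus.
#'
#' Because the wobble positions are synonymous third-codon positions, their
#' allowed alphabets are dictated by the genetic code: Val14/Gly15/Ser17/
#' Ala18/Leu19/Thr20 are fourfold degenerate, Lys16 is twofold (AAA/AAG) and
#' Ile21 is threefold (ATA/ATC/ATT). The barcode space is therefore
#' 4^6 x 2 x 3 = 24,576 and an independent per-position nucleotide frequency
#' model of that space has sum(|alphabet| - 1) = 21 free parameters.
#'
#' @param codon12_wt,codon13_wt Wild-type codons at Kras residues 12 and 13.
#' @param wobble_alphabets Optional list of 8 character vectors overriding the
#'   allowed nucleotides at each wobble position (subsets of A/C/G/T).
#'
#' @return An object of class `kras_design`: a list with the fixed core
#'   segments (`prefix`, `upstream_flank`, `spacer`, `downstream_flank`,
#'   `suffix`), the wild-type codons, the barcode-region template
#'   (`region_template`, `N` at wobble positions), `wobble_pos`,
#'   `wobble_alphabets`, `anchor_pos` and the derived core coordinates.
#' @examples
#' d <- kras_design()
#' n_barcodes(d)      # 24576
#' free_parameters(d) # 21
#' @export
kras_design <- function(codon12_wt = "GGT", codon13_wt = "GGC",
                        wobble_alphabets = NULL) {
  stopifnot(is_dna(codon12_wt, 3L), is_dna(codon13_wt, 3L))
  default_alpha <- list(
    c("A", "C", "G", "T"),  # Val14 GTN
    c("A", "C", "G", "T"),  # Gly15 GGN
    c("A", "G"),            # Lys16 AAR
    c("A", "C", "G", "T"),  # Ser17 TCN (anchor-recoded from AGT)
    c("A", "C", "G", "T"),  # Ala18 GCN
    c("A", "C", "G", "T"),  # Leu19 CTN (anchor-recoded from TTG)
    c("A", "C", "G", "T"),  # Thr20 ACN
    c("A", "C", "T")        # Ile21 ATH
  )
  if (is.null(wobble_alphabets)) {
    wobble_alphabets <- default_alpha
  } else {
    stopifnot(length(wobble_alphabets) == 8L)
    ok <- vapply(wobble_alphabets, function(a) {
      length(a) >= 1L && all(a %in% c("A", "C", "G", "T")) && !anyDuplicated(a)
    }, logical(1))
    if (!all(ok)) {
      stop("each wobble alphabet must be a non-empty duplicate-free subset of A/C/G/T",
           call. = FALSE)
    }
    wobble_alphabets <- lapply(wobble_alphabets, sort)
  }

  design <- structure(
    list(
      prefix          = "TGTGGTAGT",
      upstream_flank  = "TGGAGCT",
      codon12_wt      = codon12_wt,
      codon13_wt      = codon13_wt,
      spacer          = "GT",  # codon 14 bases 1-2, between codon 13 and barcode
      region_template = "NGGNAANTCNGCNCTNACNATN",
      region_length   = 22L,
      wobble_pos      = c(1L, 4L, 7L, 10L, 13L, 16L, 19L, 22L),
      wobble_alphabets = wobble_alphabets,
      anchor_pos      = c(8L, 9L, 14L),  # TC (Ser17) and C (Leu19), non-WT
      wt_region       = "AGGCAAGAGTGCCTTGACGATA",
      downstream_flank = "CAGCTAA",
      suffix          = "TTCAGAA",
      core_length     = 60L
    ),
    class = "kras_design"
  )
  design$coords <- core_coords(design)
  design
}

#' @export
print.kras_design <- function(x, ...) {
  cat("<kras_design>\n")
  cat("  core: ", x$core_length, " nt; barcode region: ", x$region_length,
      " nt (template ", x$region_template, ")\n", sep = "")
  cat("  wobble alphabets:",
      paste(vapply(x$wobble_alphabets, paste, "", collapse = ""), collapse = " "),
      "\n")
  cat("  barcode space:", n_barcodes(x), "| free parameters:",
      free_parameters(x), "\n")
  invisible(x)
}

# 1-based [start, end] coordinates of each core segment
core_coords <- function(design) {
  lens <- c(
    prefix = nchar(design$prefix),
    upstream_flank = nchar(design$upstream_flank),
    codon12 = 3L, codon13 = 3L,
    spacer = nchar(design$spacer),
    region = design$region_length,
    downstream_flank = nchar(design$downstream_flank),
    suffix = nchar(design$suffix)
  )
  end <- cumsum(lens)
  start <- end - lens + 1L
  stopifnot(unname(end[length(end)]) == design$core_length)
  tibble::tibble(segment = names(lens), start = unname(start), end = unname(end))
}

segment_range <- function(design, segment) {
  row <- design$coords[design$coords$segment == segment, ]
  c(row$start, row$end)
}

#' Number of barcodes a design can encode
#'
#' @param design A [kras_design()].
#' @return Product of the wobble alphabet sizes (24,576 for the default).
#' @export
n_barcodes <- function(design) {
  prod(lengths(design$wobble_alphabets))
}

#' Free parameters of the independent per-position frequency model
#'
#' @param design A [kras_design()].
#' @return `sum(|alphabet| - 1)` over wobble positions (21 for the default).
#' @export
free_parameters <- function(design) {
  sum(lengths(design$wobble_alphabets) - 1L)
}

#' Enumerate all barcodes of a design
#'
#' Lexicographic enumeration of the wobble-position strings. Intended for
#' designs up to the default 24,576-barcode space.
#'
#' @param design A [kras_design()].
#' @return Character vector of 8-character barcodes in lexicographic order.
#' @export
enumerate_barcodes <- function(design) {
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  grid <- expand.grid(rev(design$wobble_alphabets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  do.call(paste0, grid)
}

#' Enumerate non-synonymous single-nucleotide Kras codon 12/13 variants
#'
#' Generates every single-nucleotide substitution of the two wild-type codons,
#' translates with the standard genetic code, and keeps the substitutions that
#' change the encoded amino acid. For wild-type GGT/GGC this yields the 12
#' variants of the library (G12A/C/D/R/S/V and G13A/C/D/R/S/V); third-position
#' substitutions are synonymous (all encode Gly) and are excluded.
#'
#' @param codon12_wt,codon13_wt Wild-type codons (3-nt DNA strings).
#' @return A tibble with one row per variant: `variant` label (e.g. "G12D"),
#'   `residue` (12 or 13), `codon12`, `codon13` (realized codons), `aa_ref`,
#'   `aa_alt`.
#' @examples
#' enumerate_variants()  # 12 rows
#' @export
enumerate_variants <- function(codon12_wt = "GGT", codon13_wt = "GGC") {
  if (!is_dna(codon12_wt, 3L) || !is_dna(codon13_wt, 3L)) {
    stop("codons must be 3-nt DNA strings over A/C/G/T", call. = FALSE)
  }
  one_codon <- function(codon, residue) {
    aa_wt <- translate_codon(codon)
    bases <- strsplit(codon, "")[[1]]
    out <- list()
    for (pos in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), bases[pos])) {
        mut <- bases
        mut[pos] <- nt
        mut_codon <- paste(mut, collapse = "")
        aa <- translate_codon(mut_codon)
        if (aa != aa_wt) {
          out[[length(out) + 1L]] <- tibble::tibble(
            residue = residue, codon = mut_codon, aa_ref = aa_wt, aa_alt = aa
          )
        }
      }
    }
    dplyr::bind_rows(out)
  }
  res <- dplyr::bind_rows(
    one_codon(codon12_wt, 12L),
    one_codon(codon13_wt, 13L)
  )
  res$variant <- paste0(res$aa_ref, res$residue, res$aa_alt)
  res$codon12 <- ifelse(res$residue == 12L, res$codon, codon12_wt)
  res$codon13 <- ifelse(res$residue == 13L, res$codon, codon13_wt)
  res <- res[!duplicated(res$variant), ]
  tibble::as_tibble(res[, c("variant", "residue", "codon12", "codon13",
                            "aa_ref", "aa_alt")])
}

#' Allele classes of a design: wild type plus the non-synonymous variants
#'
#' @param design A [kras_design()].
#' @return Tibble like [enumerate_variants()] with a leading WT row.
#' @export
allele_classes <- function(design = kras_design()) {
  wt <- tibble::tibble(
    variant = "WT", residue = NA_integer_,
    codon12 = design$codon12_wt, codon13 = design$codon13_wt,
    aa_ref = translate_codon(design$codon12_wt),
    aa_alt = translate_codon(design$codon12_wt)
  )
  dplyr::bind_rows(wt, enumerate_variants(design$codon12_wt, design$codon13_wt))
}

#' Realize the barcode region sequence for a barcode
#'
#' Fills the design's region template with the 8 wobble bases of `barcode`.
#'
#' @param barcode Character vector of 8-character barcodes.
#' @param design A [kras_design()].
#' @return Character vector of 22-nt region sequences.
#' @export
barcode_region <- function(barcode, design = kras_design()) {
  stopifnot(all(nchar(barcode) == length(design$wobble_pos)))
  template <- strsplit(design$region_template, "")[[1]]
  vapply(barcode, function(bc) {
    region <- template
    region[design$wobble_pos] <- strsplit(bc, "")[[1]]
    paste(region, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Synthesize error-free 60-nt amplicon cores
#'
#' Inverse of [parse_reads()]: builds the full core sequence for each
#' (variant, barcode) pair. Vectorized over rows.
#'
#' @param variant Variant labels ("WT" or labels from [enumerate_variants()]).
#' @param barcode 8-character barcodes.
#' @param design A [kras_design()].
#' @return Character vector of 60-nt cores.
#' @export
synthesize_core <- function(variant, barcode, design = kras_design()) {
  classes <- allele_classes(design)
  idx <- match(variant, classes$variant)
  if (anyNA(idx)) {
    stop("unknown variant label(s): ",
         paste(unique(variant[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  paste0(
    design$prefix, design$upstream_flank,
    classes$codon12[idx], classes$codon13[idx],
    design$spacer,
    barcode_region(barcode, design),
    design$downstream_flank, design$suffix
  )
}

#' Parse amplicon cores into (variant, barcode) pairs
#'
#' Validates each 60-nt merged/trimmed core against the design: every
#' invariant base (prefix, flanks, spacer, fixed region bases including the
#' three anchors, suffix) must match exactly, codons 12/13 must decode to a
#' known allele class, and each barcode base must belong to its wobble
#' alphabet. Reads failing a check are rejected with a reason code rather
#' than raising an error.
#'
#' @param seqs Character vector of candidate 60-nt cores (sense orientation).
#' @param design A [kras_design()].
#' @return A tibble with one row per input read: `seq`, `status`
#'   ("ok"/"rejected"), `reason` (NA, or one of "bad_length",
#'   "anchor_mismatch", "unknown_codon", "bad_barcode_base"), `variant`,
#'   `barcode` (NA when rejected).
#' @export
parse_reads <- function(seqs, design = kras_design()) {
  n <- length(seqs)
  variant <- rep(NA_character_, n)
  barcode <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  ok <- !is.na(seqs) & nchar(seqs) == design$core_length
  reason[!ok] <- "bad_length"

  if (any(ok)) {
    classes <- allele_classes(design)
    codon_key <- paste0(classes$codon12, classes$codon13)

    template <- strsplit(design$region_template, "")[[1]]
    fixed_in_region <- which(template != "N")
    rg <- segment_range(design, "region")

    invariant_expected <- paste0(
      design$prefix, design$upstream_flank, design$spacer,
      paste(template[fixed_in_region], collapse = ""),
      design$downstream_flank, design$suffix
    )
    pr <- segment_range(design, "prefix")
    uf <- segment_range(design, "upstream_flank")
    sp <- segment_range(design, "spacer")
    df <- segment_range(design, "downstream_flank")
    sx <- segment_range(design, "suffix")

    s <- seqs[ok]
    invariant_observed <- paste0(
      substr(s, pr[1], pr[2]), substr(s, uf[1], uf[2]), substr(s, sp[1], sp[2]),
      vapply(strsplit(substr(s, rg[1], rg[2]), ""),
             function(x) paste(x[fixed_in_region], collapse = ""), character(1)),
      substr(s, df[1], df[2]), substr(s, sx[1], sx[2])
    )
    anchor_ok <- invariant_observed == invariant_expected

    c12 <- segment_range(design, "codon12")
    c13 <- segment_range(design, "codon13")
    codon_idx <- match(paste0(substr(s, c12[1], c12[2]),
                              substr(s, c13[1], c13[2])), codon_key)
    codon_ok <- !is.na(codon_idx)

    bc_chars <- t(vapply(strsplit(substr(s, rg[1], rg[2]), ""),
                         function(x) x[design$wobble_pos],
                         character(length(design$wobble_pos))))
    bc_ok <- rep(TRUE, length(s))
    for (k in seq_along(design$wobble_alphabets)) {
      bc_ok <- bc_ok & bc_chars[, k] %in% design$wobble_alphabets[[k]]
    }

    r <- rep(NA_character_, length(s))
    r[!bc_ok] <- "bad_barcode_base"
    r[!codon_ok] <- "unknown_codon"
    r[!anchor_ok] <- "anchor_mismatch"  # highest precedence

    pass <- is.na(r)
    v <- rep(NA_character_, length(s))
    b <- rep(NA_character_, length(s))
    v[pass] <- classes$variant[codon_idx[pass]]
    b[pass] <- apply(bc_chars[pass, , drop = FALSE], 1, paste, collapse = "")

    variant[ok] <- v
    barcode[ok] <- b
    reason[ok] <- r
  }

  tibble::tibble(
    seq = seqs,
    status = ifelse(is.na(reason), "ok", "rejected"),
    reason = reason,
    variant = variant,
    barcode = barcode
  )
}

#' The documented spike-in (normalization control) allele
#'
#' The normalization control is genomic DNA from a clonal G12V tumor cell
#' line; its wobble bases read CGGGGTGC.
#'
#' @return A list with `variant`, `barcode` and the default `cells` (5e5).
#' @export
spikein_allele <- function() {
  list(variant = "G12V", barcode = "CGGGGTGC", cells = 5e5)
}
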