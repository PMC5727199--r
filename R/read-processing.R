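#' Merge overlapping read pairs at a fixed expected fragment length
#'
#' Minimal fixed-offset merger for amplicons of known length: the reverse
#' read is reverse-complemented and aligned so that the merged fragment has
#' `fragment_length` bases. At overlap mismatches the base with the higher
#' quality wins; pairs whose overlap identity falls below `min_identity` are
#' rejected.
#'
#' @param r1,r2 Character vectors of forward and reverse reads (r2 in
#'   reverse-complement orientation, as sequenced).
#' @param q1,q2 Matching quality strings (Phred+33); constant high quality is
#'   assumed when NULL.
#' @param fragment_length Expected merged fragment length.
#' @param min_identity Minimum overlap identity (default 0.9).
#' @return Tibble `seq` (merged sequence, NA when rejected), `status`,
#'   `reason` (NA or "short_read"/"low_identity").
#' @export
merge_read_pairs <- function(r1, r2, q1 = NULL, q2 = NULL,
                             fragment_length = 60L, min_identity = 0.9) {
  stopifnot(length(r1) == length(r2))
  n <- length(r1)
  if (is.null(q1)) q1 <- strrep("F", nchar(r1))
  if (is.null(q2)) q2 <- strrep("F", nchar(r2))
  r2rc <- reverse_complement(r2)
  q2rc <- vapply(q2, function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                 character(1), USE.NAMES = FALSE)

  merged <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    l1 <- nchar(r1[i]); l2 <- nchar(r2rc[i])
    overlap <- l1 + l2 - fragment_length
    if (overlap < 1L || l1 > fragment_length || l2 > fragment_length) {
      reason[i] <- "short_read"
      next
    }
    a <- strsplit(r1[i], "")[[1]]
    b <- strsplit(r2rc[i], "")[[1]]
    qa <- utf8ToInt(q1[i]) - 33L
    qb <- utf8ToInt(q2rc[i]) - 33L
    off <- fragment_length - l2  # r2rc starts at position off+1
    ia <- (off + 1L):l1          # overlap indices in r1
    ib <- seq_len(overlap)       # overlap indices in r2rc
    ident <- mean(a[ia] == b[ib])
    if (ident < min_identity) {
      reason[i] <- "low_identity"
      next
    }
    ov <- ifelse(qa[ia] >= qb[ib], a[ia], b[ib])
    merged[i] <- paste(c(a[seq_len(off)], ov, b[(overlap + 1L):l2]),
                       collapse = "")
  }
  tibble::tibble(seq = merged,
                 status = ifelse(is.na(reason), "ok", "rejected"),
                 reason = reason)
}

#' Trim merged reads to the clustering sequence
#'
#' Locates the invariant prefix anchor and excises the clustering sequence:
#' the 7-nt flank upstream of codon 12 through the 7-nt flank downstream of
#' the final barcode base (44 nt: flank + codons 12-13 + 2-nt spacer + 22-nt
#' barcode region + flank). Reads with any base below `min_quality` inside
#' the clustering window, a missing prefix, or the wrong length are rejected.
#'
#' @param seqs Merged sequences (expected 60-nt cores).
#' @param design A [kras_design()].
#' @param qual Optional quality strings aligned with `seqs`.
#' @param min_quality Minimum per-base Phred quality inside the window.
#' @return Tibble `seq` (44-nt clustering sequence or NA), `status`,
#'   `reason` (NA or "bad_length"/"no_primer"/"low_quality").
#' @export
filter_and_trim <- function(seqs, design = kras_design(), qual = NULL,
                            min_quality = 20L) {
  n <- length(seqs)
  reason <- rep(NA_character_, n)
  out <- rep(NA_character_, n)

  len_ok <- !is.na(seqs) & nchar(seqs) == design$core_length
  reason[!len_ok] <- "bad_length"

  primer_ok <- len_ok & startsWith(ifelse(is.na(seqs), "", seqs), design$prefix)
  reason[len_ok & !primer_ok] <- "no_primer"

  win <- clustering_window(design)
  if (!is.null(qual)) {
    qwin <- substr(qual, win[1], win[2])
    minq <- vapply(qwin, function(q) {
      if (is.na(q) || nchar(q) == 0L) return(Inf)
      min(utf8ToInt(q) - 33L)
    }, numeric(1), USE.NAMES = FALSE)
    low <- primer_ok & minq < min_quality
    reason[low] <- "low_quality"
    primer_ok <- primer_ok & !low
  }

  out[primer_ok] <- substr(seqs[primer_ok], win[1], win[2])
  tibble::tibble(seq = out,
                 status = ifelse(is.na(reason), "ok", "rejected"),
                 reason = reason)
}

# core coordinates [start, end] of the clustering sequence
clustering_window <- function(design) {
  c(segment_range(design, "upstream_flank")[1],
    segment_range(design, "downstream_flank")[2])
}

# length of the clustering sequence (44 for the default design)
clustering_length <- function(design) {
  w <- clustering_window(design)
  w[2] - w[1] + 1L
}

#' Error-free clustering sequence of a (variant, barcode) pair
#'
#' The 44-nt sequence [denoise_pileup()] operates on, synthesized directly
#' from an allele (useful for building test pileups and expected centers).
#'
#' @param variant,barcode Allele specification (vectorized).
#' @param design A [kras_design()].
#' @return Character vector of 44-nt clustering sequences.
#' @export
clustering_seq <- function(variant, barcode, design = kras_design()) {
  w <- clustering_window(design)
  substr(synthesize_core(variant, barcode, design), w[1], w[2])
}

#' Tally clustering sequences into a sample pileup
#'
#' Exact multiset count of equal-length sequences; order-independent.
#'
#' @param seqs Character vector of clustering sequences (NAs dropped).
#' @param sample Optional sample label column to attach.
#' @return Tibble `seq`, `count`, sorted by decreasing count then sequence.
#' @export
tally_pileup <- function(seqs, sample = NULL) {
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0L) {
    out <- tibble::tibble(seq = character(), count = integer())
  } else {
    stopifnot(length(unique(nchar(seqs))) == 1L)
    out <- dplyr::count(tibble::tibble(seq = seqs), .data$seq, name = "count")
    out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$seq)
  }
  if (!is.null(sample)) out <- dplyr::mutate(out, sample = sample, .before = 1)
  out
}

#' Estimate the residual per-base error rate from invariant flanks
#'
#' The 7 nt upstream of codon 12 and the 7 nt downstream of the final
#' barcode base are invariant by design, so every mismatch observed there is
#' a sequencing/PCR error. The estimate is the read-count-weighted fraction
#' of mismatching flank bases.
#'
#' @param pileup Tibble `seq`, `count` of clustering sequences from
#'   [tally_pileup()].
#' @param design A [kras_design()].
#' @return Per-base error rate (scalar).
#' @export
estimate_error_rate <- function(pileup, design = kras_design()) {
  if (nrow(pileup) == 0L) stop("empty pileup", call. = FALSE)
  len <- clustering_length(design)
  stopifnot(all(nchar(pileup$seq) == len))
  up_len <- nchar(design$upstream_flank)
  down_len <- nchar(design$downstream_flank)
  flank_obs <- paste0(substr(pileup$seq, 1L, up_len),
                      substr(pileup$seq, len - down_len + 1L, len))
  expected <- strsplit(paste0(design$upstream_flank, design$downstream_flank),
                       "")[[1]]
  mism <- vapply(strsplit(flank_obs, ""),
                 function(x) sum(x != expected), numeric(1))
  sum(mism * pileup$count) / (length(expected) * sum(pileup$count))
}

#' Process reads of one sample into a pileup with accounting
#'
#' Convenience wrapper: [filter_and_trim()] then [tally_pileup()], returning
#' the pileup together with accept/reject totals by reason.
#'
#' @param seqs Merged read sequences.
#' @param design A [kras_design()].
#' @param qual,min_quality Passed to [filter_and_trim()].
#' @return List with `pileup` (tibble seq, count) and `accounting`
#'   (tibble reason, reads; reason "accepted" for kept reads).
#' @export
process_reads <- function(seqs, design = kras_design(), qual = NULL,
                          min_quality = 20L) {
  trimmed <- filter_and_trim(seqs, design, qual = qual,
                             min_quality = min_quality)
  accounting <- dplyr::count(
    tibble::tibble(reason = ifelse(trimmed$status == "ok",
                                   "accepted", trimmed$reason)),
    .data$reason, name = "reads"
  )
  list(pileup = tally_pileup(trimmed$seq), accounting = accounting)
}
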