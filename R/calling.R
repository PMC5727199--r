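#' Call tumors in one sample from a read pileup
#'
#' Runs the per-sample calling chain: estimate the residual error rate from
#' the invariant flanks (unless supplied), denoise the pileup
#' ([denoise_pileup()]), remove shadow calls ([remove_shadows()]), parse the
#' surviving cluster centers into (variant, barcode) pairs, and — in lung
#' mode — convert reads to absolute cell numbers via the spike-in
#' ([normalize_to_spikein()]).
#'
#' @param pileup Tibble `seq`, `count` of clustering sequences.
#' @param sample Sample identifier attached to the calls.
#' @param design A [kras_design()].
#' @param mode "lung" (spike-in normalization to absolute cells) or
#'   "pancreas" (no spike-in; sizes stay in reads).
#' @param error_rate Per-base error rate; estimated from the pileup flanks
#'   when NULL.
#' @param omega_a Abundance p-value threshold for [denoise_pileup()].
#' @param shadow_ratio,shadow_distance Passed to [remove_shadows()].
#' @param spikein Spike-in specification (list `variant`, `barcode`,
#'   `cells`), default [spikein_allele()].
#' @return Tibble of calls: `sample`, `variant`, `barcode`, `reads`, `cells`
#'   (NA in pancreas mode), `is_spikein`; attributes `error_rate` and
#'   `shadow_fraction`. Cluster centers that fail allele parsing are dropped
#'   (attribute `n_unparsed`).
#' @export
call_tumors <- function(pileup, sample = "sample", design = kras_design(),
                        mode = c("lung", "pancreas"), error_rate = NULL,
                        omega_a = 0.01, shadow_ratio = 1e4,
                        shadow_distance = 1L, spikein = spikein_allele()) {
  mode <- match.arg(mode)
  if (is.null(error_rate)) error_rate <- estimate_error_rate(pileup, design)

  clusters <- denoise_pileup(pileup, error_rate, omega_a = omega_a)
  clusters <- remove_shadows(clusters, ratio_threshold = shadow_ratio,
                             distance = shadow_distance)
  shadow_fraction <- attr(clusters, "removed_fraction")

  # the clustering sequence is the core minus prefix/suffix: parse by
  # re-embedding it in the invariant context
  cores <- paste0(design$prefix, clusters$center, design$suffix)
  parsed <- parse_reads(cores, design)
  keep <- parsed$status == "ok"

  calls <- tibble::tibble(
    sample = sample,
    variant = parsed$variant[keep],
    barcode = parsed$barcode[keep],
    reads = clusters$reads[keep],
    cells = NA_real_,
    is_spikein = FALSE
  )
  if (mode == "lung") {
    calls <- normalize_to_spikein(calls, spikein = spikein)
  }
  attr(calls, "error_rate") <- error_rate
  attr(calls, "shadow_fraction") <- shadow_fraction
  attr(calls, "n_unparsed") <- sum(!keep)
  calls
}

#' Convert read counts to absolute cell numbers via the spike-in
#'
#' The normalization control is DNA from a known number of cells with a
#' known variant-barcode pair, added to each bulk sample before extraction.
#' Each call's cell number is `reads / spikein_reads * spikein_cells`; the
#' spike-in call itself is flagged and excluded from downstream tumor sets.
#'
#' @param calls Tibble with `sample`, `variant`, `barcode`, `reads`.
#' @param spikein List `variant`, `barcode`, `cells` (default
#'   [spikein_allele()]).
#' @return `calls` with `cells` filled in and `is_spikein` set.
#' @export
normalize_to_spikein <- function(calls, spikein = spikein_allele()) {
  per_sample <- lapply(split(calls, calls$sample), function(cc) {
    is_sp <- cc$variant == spikein$variant & cc$barcode == spikein$barcode
    if (!any(is_sp)) {
      stop("no spike-in call (", spikein$variant, "/", spikein$barcode,
           ") in sample ", cc$sample[1], call. = FALSE)
    }
    sp_reads <- sum(cc$reads[is_sp])
    cc$cells <- cc$reads / sp_reads * spikein$cells
    cc$is_spikein <- is_sp
    cc
  })
  dplyr::bind_rows(per_sample)
}

#' Apply the minimum-size cutoff to tumor calls
#'
#' Lung mode keeps calls strictly above `min_cells` absolute cells (the
#' spike-in is excluded first). Pancreas mode has no absolute scale and
#' instead keeps calls with reads strictly above twice the largest wild-type
#' call in the same sample; a sample without any WT call gets threshold 0
#' with a warning.
#'
#' @param calls Tibble of calls (with `cells` in lung mode).
#' @param mode "lung" or "pancreas".
#' @param min_cells Lung-mode cell cutoff (default 1e5).
#' @return List with `kept` and `dropped` call tibbles.
#' @export
apply_size_cutoff <- function(calls, mode = c("lung", "pancreas"),
                              min_cells = 1e5) {
  mode <- match.arg(mode)
  if (nrow(calls) == 0L) return(list(kept = calls, dropped = calls))
  if (!is.null(calls[["is_spikein"]])) calls <- calls[!calls$is_spikein, ]
  if (mode == "lung") {
    keep <- calls$cells > min_cells
  } else {
    thr <- vapply(split(calls, calls$sample), function(cc) {
      wt <- cc$reads[cc$variant == "WT"]
      if (length(wt) == 0L) {
        warning("no WT call in sample ", cc$sample[1],
                "; pancreas cutoff threshold is 0", call. = FALSE)
        0
      } else 2 * max(wt)
    }, numeric(1))
    keep <- calls$reads > thr[calls$sample]
  }
  list(kept = calls[keep, ], dropped = calls[!keep, ])
}

#' Concordance of tumor sizes between technical replicates
#'
#' Least-squares R-squared of log10 cell numbers over the (variant, barcode)
#' pairs shared by two call sets.
#'
#' @param calls_a,calls_b Call tibbles with `variant`, `barcode`, `cells`.
#' @return A tibble `n_shared`, `r_squared`.
#' @export
replicate_concordance <- function(calls_a, calls_b) {
  shared <- dplyr::inner_join(
    calls_a[, c("variant", "barcode", "cells")],
    calls_b[, c("variant", "barcode", "cells")],
    by = c("variant", "barcode"), suffix = c("_a", "_b")
  )
  if (nrow(shared) < 3L) {
    stop("need at least 3 shared (variant, barcode) pairs", call. = FALSE)
  }
  fit <- stats::lm(log10(cells_b) ~ log10(cells_a), data = shared)
  tibble::tibble(n_shared = nrow(shared),
                 r_squared = summary(fit)$r.squared)
}
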