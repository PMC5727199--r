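#' Per-variant representation of the plasmid pool
#'
#' Fraction of library reads carrying each variant after removing barcodes
#' above the `trim_percentile` of per-barcode read abundance (computed
#' pool-wide), so that extremely abundant variant-barcode pairs do not
#' dominate a variant's representation.
#'
#' @param pool Plasmid pool tibble (`variant`, `barcode`, `reads`).
#' @param trim_percentile Percentile above which barcodes are dropped
#'   (default 98).
#' @return Tibble `variant`, `reads` (trimmed totals), `fraction` (sums
#'   to 1).
#' @export
variant_representation <- function(pool, trim_percentile = 98) {
  per_bc <- dplyr::summarise(dplyr::group_by(pool, .data$barcode),
                             reads = sum(.data$reads), .groups = "drop")
  cutoff <- stats::quantile(per_bc$reads, trim_percentile / 100,
                            names = FALSE, type = 7)
  keep_bc <- per_bc$barcode[per_bc$reads <= cutoff]
  trimmed <- pool[pool$barcode %in% keep_bc, ]
  rep_tbl <- dplyr::summarise(dplyr::group_by(trimmed, .data$variant),
                              reads = sum(.data$reads), .groups = "drop")
  rep_tbl$fraction <- rep_tbl$reads / sum(rep_tbl$reads)
  rep_tbl
}

#' Normalized tumor number per variant, relative to wild type
#'
#' Tumor counts are divided by each variant's initial library representation
#' and scaled so that wild type has value 1:
#' `value_v = (count_v / rep_v) / (count_WT / rep_WT)`. When no WT tumors
#' were observed (a structural zero), the representation-normalized counts
#' are returned unscaled with `wt_scaled = FALSE`.
#'
#' @param counts Tibble `variant`, `n` of tumor counts (e.g. above-cutoff
#'   calls per variant), or a call tibble with a `variant` column (counted
#'   internally).
#' @param representation Tibble from [variant_representation()].
#' @return Tibble `variant`, `n`, `fraction` (representation),
#'   `normalized` (count / representation) and `relative` (WT = 1), plus the
#'   logical `wt_scaled` attribute-column.
#' @export
normalized_tumor_number <- function(counts, representation) {
  if (!("n" %in% names(counts))) {
    counts <- dplyr::count(counts, .data$variant)
  }
  out <- dplyr::left_join(representation[, c("variant", "fraction")], counts,
                          by = "variant")
  out$n[is.na(out$n)] <- 0L
  if (any(out$fraction <= 0)) stop("non-positive representation", call. = FALSE)
  out$normalized <- out$n / out$fraction
  wt <- out$normalized[out$variant == "WT"]
  if (length(wt) == 1L && wt > 0) {
    out$relative <- out$normalized / wt
    out$wt_scaled <- TRUE
  } else {
    out$relative <- out$normalized
    out$wt_scaled <- FALSE
  }
  out
}

#' Two-sided Fisher's exact test of a variant against a reference allele
#'
#' Tests whether `count_v` tumors against `count_ref` is consistent with the
#' two alleles' library representation (in raw reads), via the exact
#' hypergeometric test on the 2x2 table
#' `[[count_v, count_ref], [rep_reads_v, rep_reads_ref]]` (two-sided: sum of
#' table probabilities not exceeding the observed one). The Bonferroni
#' correction multiplies by the number of variants investigated.
#'
#' @param count_v,count_ref Tumor counts (non-negative integers).
#' @param rep_reads_v,rep_reads_ref Library read counts of the two alleles.
#' @param n_variants Bonferroni multiplier (default 12 mutant variants).
#' @return Tibble `p_value`, `p_adjusted`.
#' @export
fisher_vs_reference <- function(count_v, count_ref, rep_reads_v,
                                rep_reads_ref, n_variants = 12L) {
  tbl <- matrix(c(count_v, count_ref, rep_reads_v, rep_reads_ref),
                nrow = 2, byrow = TRUE)
  stopifnot(all(tbl >= 0))
  if (sum(tbl[1, ]) == 0 || sum(tbl[2, ]) == 0 ||
      sum(tbl[, 1]) == 0 || sum(tbl[, 2]) == 0) {
    p <- 1
  } else {
    p <- stats::fisher.test(tbl, alternative = "two.sided")$p.value
  }
  tibble::tibble(p_value = p, p_adjusted = min(1, p * n_variants))
}

#' Exact enrichment test against a structurally zero reference
#'
#' When no reference (wild-type) tumors were observed at all, the 2x2 Fisher
#' table degenerates. Under the null that each observed tumor is reference
#' vs variant in proportion to library representation, the probability of
#' seeing zero reference tumors among `count_v` is binomial:
#' `p1 = (1 - p_ref)^count_v` with
#' `p_ref = rep_fraction_ref / (rep_fraction_ref + rep_fraction_v)`. The
#' two-sided p-value is reported as `min(1, 2 * p1)`.
#'
#' @param count_v Observed tumors of the variant.
#' @param rep_fraction_v,rep_fraction_ref Library representation fractions.
#' @param n_variants Bonferroni multiplier (default 12).
#' @return Tibble `p_one_sided`, `p_value` (two-sided), `p_adjusted`.
#' @export
structural_zero_test <- function(count_v, rep_fraction_v, rep_fraction_ref,
                                 n_variants = 12L) {
  stopifnot(count_v >= 0, rep_fraction_v > 0, rep_fraction_ref > 0)
  if (count_v == 0) {
    p1 <- 1
  } else {
    p_ref <- rep_fraction_ref / (rep_fraction_ref + rep_fraction_v)
    p1 <- (1 - p_ref)^count_v
  }
  p2 <- min(1, 2 * p1)
  tibble::tibble(p_one_sided = p1, p_value = p2,
                 p_adjusted = min(1, p2 * n_variants))
}

#' Pearson chi-square comparison of variant spectra across genotypes
#'
#' Standard two-sided "many cells" Pearson chi-square on a variant-by-
#' genotype contingency table of tumor counts (no continuity correction). A
#' warning is logged when any expected cell is below 1, but the statistic is
#' still computed.
#'
#' @param table Matrix or data frame of tumor counts, variants in rows,
#'   genotypes in columns (at least 2 columns).
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
genotype_spectrum_chisq <- function(table) {
  m <- as.matrix(table)
  stopifnot(ncol(m) >= 2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 1)) {
    warning("expected cell count below 1; chi-square approximation is weak",
            call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value)
}

#' Bootstrap confidence intervals on relative tumor numbers
#'
#' Resamples the pooled tumor list (variant labels of individual tumors)
#' with replacement and recomputes [normalized_tumor_number()] each time;
#' percentile intervals at `level`.
#'
#' @param calls Call tibble with a `variant` column (one row per tumor).
#' @param representation Tibble from [variant_representation()].
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Tibble `variant`, `relative`, `ci_lo`, `ci_hi`.
#' @export
bootstrap_ci <- function(calls, representation, n_boot = 2000,
                         level = 0.95, seed = NULL) {
  variants <- representation$variant
  labels <- calls$variant
  point <- normalized_tumor_number(calls, representation)
  alpha <- (1 - level) / 2
  with_seed_or_not(seed, {
    boot <- matrix(NA_real_, n_boot, length(variants),
                   dimnames = list(NULL, variants))
    for (b in seq_len(n_boot)) {
      res <- labels[sample.int(length(labels), replace = TRUE)]
      cnt <- tibble::tibble(variant = variants,
                            n = as.integer(table(factor(res, variants))))
      boot[b, ] <- normalized_tumor_number(cnt, representation)$relative
    }
    ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    tibble::tibble(
      variant = variants,
      relative = point$relative[match(variants, point$variant)],
      ci_lo = ci[1, ], ci_hi = ci[2, ]
    )
  })
}

#' Correlation between plasmid-library and observed allele frequencies
#'
#' High correlation between the initial library representation and the
#' frequencies of alleles recovered in tumors indicates little to no bias in
#' which alleles undergo homology-directed repair.
#'
#' @param plasmid_freqs,observed_freqs Equal-length per-allele frequency
#'   vectors (aligned).
#' @return Tibble `r` (Pearson), `r_squared`.
#' @export
hdr_bias_correlation <- function(plasmid_freqs, observed_freqs) {
  stopifnot(length(plasmid_freqs) == length(observed_freqs))
  if (stats::sd(plasmid_freqs) == 0 || stats::sd(observed_freqs) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(plasmid_freqs, observed_freqs)
  tibble::tibble(r = r, r_squared = r^2)
}

#' Per-variant oncogenicity summary
#'
#' Combines tumor counts, library representation, wild-type-relative
#' normalized tumor numbers, bootstrap confidence intervals, and Fisher
#' tests against the WT and G12D reference alleles (Bonferroni-corrected for
#' the number of mutant variants).
#'
#' @param calls Above-cutoff call tibble (one row per tumor; `variant`).
#' @param pool Plasmid pool tibble.
#' @param trim_percentile Passed to [variant_representation()].
#' @param n_boot,level,seed Passed to [bootstrap_ci()].
#' @return A tibble of class `variant_summary`: `variant`, `n`, `fraction`,
#'   `normalized`, `relative`, `ci_lo`, `ci_hi`, `p_vs_wt`, `p_vs_g12d`
#'   (both Bonferroni-corrected), `wt_scaled`.
#' @export
variant_summary <- function(calls, pool, trim_percentile = 98,
                            n_boot = 2000, level = 0.95, seed = NULL) {
  representation <- variant_representation(pool, trim_percentile)
  base <- normalized_tumor_number(calls, representation)
  ci <- bootstrap_ci(calls, representation, n_boot = n_boot, level = level,
                     seed = seed)
  out <- dplyr::left_join(base, ci[, c("variant", "ci_lo", "ci_hi")],
                          by = "variant")

  n_mut <- sum(out$variant != "WT")
  test_vs <- function(ref) {
    ref_row <- out[out$variant == ref, ]
    vapply(seq_len(nrow(out)), function(i) {
      if (out$variant[i] == ref) return(NA_real_)
      if (ref == "WT" && (nrow(ref_row) == 0L || ref_row$n == 0)) {
        return(structural_zero_test(out$n[i], out$fraction[i],
                                    ref_row$fraction, n_mut)$p_adjusted)
      }
      fisher_vs_reference(out$n[i], ref_row$n,
                          representation$reads[representation$variant == out$variant[i]],
                          representation$reads[representation$variant == ref],
                          n_mut)$p_adjusted
    }, numeric(1))
  }
  out$p_vs_wt <- test_vs("WT")
  out$p_vs_g12d <- if ("G12D" %in% out$variant) test_vs("G12D") else NA_real_
  class(out) <- c("variant_summary", class(out))
  out
}
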