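#' Run the full tumor-calling and oncogenicity pipeline
#'
#' End-to-end orchestration over in-memory tables: per-sample read
#' processing ([process_reads()]), tumor calling ([call_tumors()]), barcode
#' collision correction ([correct_collisions_by_sample()]), the size cutoff
#' ([apply_size_cutoff()]) and the per-variant summary ([variant_summary()]).
#' With `out_dir` set, all intermediates are written as TSV plus a JSON
#' manifest of the configuration.
#'
#' @param reads Tibble `sample`, `seq` of merged amplicon reads (e.g. from
#'   [simulate_sample_reads()] or [read_fastq()]).
#' @param pool Plasmid pool tibble (`variant`, `barcode`, `reads`).
#' @param design A [kras_design()].
#' @param mode "lung" (spike-in, absolute cells) or "pancreas".
#' @param omega_a,shadow_ratio Denoising thresholds (see [call_tumors()]).
#' @param min_cells Lung size cutoff (cells).
#' @param trim_percentile Representation trim (see
#'   [variant_representation()]).
#' @param exclusion_fraction Over-represented barcode exclusion (see
#'   [exclude_frequent_barcodes()]).
#' @param spikein Spike-in specification (default [spikein_allele()]).
#' @param dissected Optional tibble `sample`, `variant`, `barcode` of
#'   individually dissected tumors: flagged and excluded from size-based
#'   output (`calls$excluded_dissected`) but retained in tumor counts.
#' @param n_boot,seed Bootstrap settings for the summary.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return Object of class `tubaseq_run`: list with `calls` (all corrected
#'   calls), `kept`/`dropped` (cutoff result), `summary`
#'   (`variant_summary`), `collision_estimates`, `accounting`,
#'   `error_rates`, `shadow_fractions`, `freq_model`, `config`.
#' @export
run_pipeline <- function(reads, pool, design = kras_design(),
                         mode = c("lung", "pancreas"),
                         omega_a = 0.01, shadow_ratio = 1e4,
                         min_cells = 1e5, trim_percentile = 98,
                         exclusion_fraction = 0.10,
                         spikein = spikein_allele(), dissected = NULL,
                         n_boot = 2000, seed = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  config <- list(mode = mode, omega_a = omega_a, shadow_ratio = shadow_ratio,
                 min_cells = min_cells, trim_percentile = trim_percentile,
                 exclusion_fraction = exclusion_fraction,
                 spikein = spikein, n_boot = n_boot, seed = seed)

  # stage 1: per-sample processing and calling
  accounting <- list(); error_rates <- c(); shadow_fractions <- c()
  calls <- lapply(split(reads$seq, reads$sample), function(s) NULL)
  for (smp in names(calls)) {
    proc <- process_reads(reads$seq[reads$sample == smp], design)
    cc <- call_tumors(proc$pileup, sample = smp, design = design,
                      mode = mode, omega_a = omega_a,
                      shadow_ratio = shadow_ratio, spikein = spikein)
    accounting[[smp]] <- dplyr::mutate(proc$accounting, sample = smp,
                                       .before = 1)
    error_rates[smp] <- attr(cc, "error_rate")
    shadow_fractions[smp] <- attr(cc, "shadow_fraction")
    calls[[smp]] <- cc
  }
  calls <- dplyr::bind_rows(calls)

  # stage 2: collision model from the plasmid library
  freq_model <- fit_barcode_frequencies(pool, design)
  freq_model <- exclude_frequent_barcodes(freq_model, pool,
                                          fraction = exclusion_fraction)
  corrected <- correct_collisions_by_sample(calls, freq_model)
  calls <- corrected$calls

  # stage 3: dissected-tumor flag, cutoff, per-variant summary
  calls$excluded_dissected <- FALSE
  if (!is.null(dissected)) {
    key <- paste(calls$sample, calls$variant, calls$barcode)
    dkey <- paste(dissected$sample, dissected$variant, dissected$barcode)
    calls$excluded_dissected <- key %in% dkey
  }
  cut <- apply_size_cutoff(calls, mode = mode, min_cells = min_cells)
  summary <- variant_summary(cut$kept, pool,
                             trim_percentile = trim_percentile,
                             n_boot = n_boot, seed = seed)

  run <- structure(
    list(calls = calls, kept = cut$kept, dropped = cut$dropped,
         summary = summary, collision_estimates = corrected$estimates,
         accounting = dplyr::bind_rows(accounting),
         error_rates = error_rates, shadow_fractions = shadow_fractions,
         freq_model = freq_model, config = config),
    class = "tubaseq_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.tubaseq_run <- function(x, ...) {
  cat("<tubaseq_run> ", length(unique(x$calls$sample)), " sample(s), ",
      nrow(x$calls), " calls (", nrow(x$kept), " above cutoff)\n", sep = "")
  cat("  mean error rate: ", format(mean(x$error_rates), digits = 3),
      "; mean shadow fraction: ",
      format(mean(x$shadow_fractions), digits = 3), "\n", sep = "")
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$calls, file.path(out_dir, "tumor_calls.tsv"))
  readr::write_tsv(run$kept, file.path(out_dir, "tumor_calls_above_cutoff.tsv"))
  readr::write_tsv(run$summary, file.path(out_dir, "variant_summary.tsv"))
  readr::write_tsv(run$collision_estimates,
                   file.path(out_dir, "collision_estimates.tsv"))
  readr::write_tsv(run$accounting, file.path(out_dir, "read_accounting.tsv"))
  manifest <- c(run$config,
                list(error_rates = as.list(run$error_rates),
                     shadow_fractions = as.list(run$shadow_fractions)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Somatic HDR efficiency from tumor-number comparison
#'
#' Mice whose tumors require an HDR event (undiluted virus) are compared
#' with mice carrying a Cre-activated oncogenic allele transduced with
#' virus diluted `dilution`-fold: every transduced cell of the latter
#' carries the oncogene, so
#' `HDR% = (tumors_hdr / tumors_cre) / dilution / oncogenic_fraction * 100`,
#' where `oncogenic_fraction` is the fraction of library alleles able to
#' drive a tumor.
#'
#' @param tumors_hdr Mean tumor count in HDR mice (undiluted virus).
#' @param tumors_cre Mean tumor count in Cre-only mice (diluted virus).
#' @param dilution Fold dilution of the Cre-only virus (>= 1).
#' @param oncogenic_fraction Fraction of library alleles that are oncogenic
#'   (0 < f <= 1).
#' @return HDR frequency in percent.
#' @examples
#' hdr_efficiency(2, 1, 1e4, 1)    # 0.02
#' hdr_efficiency(2, 1, 1e4, 0.2)  # 0.1
#' @export
hdr_efficiency <- function(tumors_hdr, tumors_cre, dilution,
                           oncogenic_fraction = 1) {
  stopifnot(tumors_hdr > 0, tumors_cre > 0, dilution >= 1,
            oncogenic_fraction > 0, oncogenic_fraction <= 1)
  (tumors_hdr / tumors_cre) / dilution / oncogenic_fraction * 100
}
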