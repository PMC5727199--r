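#' Default per-position nucleotide weights of the plasmid pool
#'
#' Barcode synthesis leaves each wobble position with mildly unequal
#' nucleotide concentrations; the same fixed, position-independent skew is
#' applied to every wobble alphabet (truncated to the alphabet and
#' renormalized). Pass `uniform = TRUE` for an unskewed pool.
#'
#' @param design A [kras_design()].
#' @param uniform If TRUE, equal weights within each alphabet.
#' @return List of 8 numeric weight vectors aligned with the wobble alphabets.
#' @export
default_position_weights <- function(design = kras_design(), uniform = FALSE) {
  base <- c(0.32, 0.27, 0.23, 0.18)
  lapply(design$wobble_alphabets, function(a) {
    w <- if (uniform) rep(1, length(a)) else base[seq_along(a)]
    w / sum(w)
  })
}

validate_weights <- function(skew, design) {
  stopifnot(length(skew) == length(design$wobble_alphabets))
  for (k in seq_along(skew)) {
    w <- skew[[k]]
    if (length(w) != length(design$wobble_alphabets[[k]]) ||
        any(w < 0) || sum(w) <= 0) {
      stop("invalid nucleotide weights at wobble position ", k, call. = FALSE)
    }
  }
  lapply(skew, function(w) w / sum(w))
}

#' Simulate sequencing of the plasmid barcode library
#'
#' Draws `depth` reads from the vector pool: the variant marginal gives the
#' wild-type allele `wt_factor` times the weight of each mutant (the pool is
#' assembled with WT over-represented about fourfold), and barcodes are drawn
#' with independent per-position nucleotide weights.
#'
#' @param design A [kras_design()].
#' @param wt_factor Ratio of WT to per-mutant representation (default 4).
#' @param depth Total library reads to draw.
#' @param skew List of per-position weight vectors (see
#'   [default_position_weights()]); NULL for the default mild skew.
#' @param seed Optional integer seed (draws are reproducible given a seed).
#' @return A tibble `variant`, `barcode`, `reads` (one row per observed pair).
#' @export
simulate_plasmid_pool <- function(design = kras_design(), wt_factor = 4,
                                  depth = 5e5, skew = NULL, seed = NULL) {
  stopifnot(depth > 0, wt_factor > 0)
  skew <- validate_weights(skew %||% default_position_weights(design), design)
  classes <- allele_classes(design)
  vweights <- ifelse(classes$variant == "WT", wt_factor, 1)

  with_seed_or_not(seed, {
    variant <- sample(classes$variant, depth, replace = TRUE,
                      prob = vweights / sum(vweights))
    bc_cols <- lapply(seq_along(design$wobble_alphabets), function(k) {
      sample(design$wobble_alphabets[[k]], depth, replace = TRUE,
             prob = skew[[k]])
    })
    barcode <- do.call(paste0, bc_cols)
    dplyr::count(tibble::tibble(variant = variant, barcode = barcode),
                 .data$variant, .data$barcode, name = "reads")
  })
}

#' Default per-variant oncogenicity multipliers
#'
#' A fixed spread used by the recovery simulations: potent codon 12 alleles,
#' weaker codon 13 alleles, and a near-zero wild-type multiplier (WT alleles
#' essentially never seed tumors).
#'
#' @return Named numeric vector over the 13 allele classes.
#' @export
default_multipliers <- function() {
  c(WT = 0.05,
    G12D = 10, G12V = 8, G12R = 6, G12C = 5, G12A = 3, G12S = 2,
    G13R = 3, G13D = 1.5, G13A = 1, G13C = 1, G13S = 0.5, G13V = 0.5)
}

#' Simulate a tumor-bearing mouse cohort with ground truth
#'
#' Each tumor's variant is drawn proportionally to (pool representation x
#' oncogenicity multiplier); its barcode is drawn from the pool's conditional
#' barcode distribution for that variant, with replacement, so barcode
#' collisions arise naturally. Tumor sizes are iid lognormal truncated below
#' at `min_cells`.
#'
#' @param pool Plasmid pool tibble from [simulate_plasmid_pool()].
#' @param multipliers Named per-variant oncogenicity multipliers (>= 0).
#' @param n_mice Number of mice.
#' @param mean_tumors Mean tumors per mouse (Poisson).
#' @param size_meanlog,size_sdlog Natural-log parameters of the tumor size
#'   distribution (defaults: median 2e5 cells, sd of log10 size = 0.5).
#' @param min_cells Lower truncation of tumor size (cells).
#' @param genotype Genotype label(s), recycled across mice.
#' @param spikein_cells Cells represented by the normalization control.
#' @param seed Optional integer seed.
#' @return A `truth_set`: list with `tumors` (tibble mouse, genotype,
#'   tumor_id, variant, barcode, cells), `spikein` (list variant, barcode,
#'   cells) and `params`.
#' @export
simulate_cohort <- function(pool, multipliers = default_multipliers(),
                            n_mice = 15, mean_tumors = 500,
                            size_meanlog = log(2e5),
                            size_sdlog = 0.5 * log(10),
                            min_cells = 1e3,
                            genotype = "PT", spikein_cells = 5e5,
                            seed = NULL) {
  stopifnot(all(multipliers >= 0), n_mice >= 1)
  if (all(multipliers == 0)) stop("all multipliers are zero", call. = FALSE)
  variants <- sort(unique(pool$variant))
  if (!all(variants %in% names(multipliers))) {
    stop("multipliers missing for: ",
         paste(setdiff(variants, names(multipliers)), collapse = ", "),
         call. = FALSE)
  }
  rep_reads <- tapply(pool$reads, pool$variant, sum)[variants]
  vprob <- rep_reads * multipliers[variants]
  genotype <- rep_len(genotype, n_mice)

  by_variant <- split(pool, pool$variant)

  with_seed_or_not(seed, {
    mice <- lapply(seq_len(n_mice), function(m) {
      n_t <- stats::rpois(1, mean_tumors)
      if (n_t == 0L) return(NULL)
      v <- sample(variants, n_t, replace = TRUE, prob = vprob / sum(vprob))
      bc <- vapply(v, function(vv) {
        pv <- by_variant[[vv]]
        pv$barcode[sample.int(nrow(pv), 1L, prob = pv$reads)]
      }, character(1), USE.NAMES = FALSE)
      # lognormal truncated below at min_cells by inverse-cdf sampling
      lo <- stats::plnorm(min_cells, size_meanlog, size_sdlog)
      u <- stats::runif(n_t, lo, 1)
      cells <- round(stats::qlnorm(u, size_meanlog, size_sdlog))
      tibble::tibble(
        mouse = sprintf("mouse_%02d", m), genotype = genotype[m],
        tumor_id = sprintf("mouse_%02d_t%04d", m, seq_len(n_t)),
        variant = v, barcode = bc, cells = cells
      )
    })
    structure(
      list(
        tumors = dplyr::bind_rows(mice),
        spikein = utils::modifyList(spikein_allele(),
                                    list(cells = spikein_cells)),
        params = list(multipliers = multipliers, n_mice = n_mice,
                      mean_tumors = mean_tumors, size_meanlog = size_meanlog,
                      size_sdlog = size_sdlog, min_cells = min_cells)
      ),
      class = "truth_set"
    )
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set> ", nrow(x$tumors), " tumors in ",
      length(unique(x$tumors$mouse)), " mice; spike-in ",
      x$spikein$variant, "/", x$spikein$barcode, " (",
      format(x$spikein$cells, big.mark = ","), " cells)\n", sep = "")
  invisible(x)
}

#' Write a truth set's tumor table to TSV
#'
#' @param truth A `truth_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth$tumors, path)
  invisible(path)
}

# substitute random erroneous bases into reads at a per-base rate
inject_errors <- function(reads, error_rate, seed_offset_ok = TRUE) {
  if (error_rate == 0 || length(reads) == 0L) return(reads)
  stopifnot(error_rate >= 0, error_rate < 0.25)
  len <- nchar(reads[1])
  k <- stats::rbinom(length(reads), len, error_rate)
  hit <- which(k > 0L)
  nts <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(len, k[i])
    chars <- strsplit(reads[i], "")[[1]]
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(nts, b), 1L),
                         character(1), USE.NAMES = FALSE)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate merged amplicon reads for every mouse of a truth set
#'
#' Emits pre-merged 60-nt amplicon cores. Per-lesion read counts are
#' multinomial with probabilities proportional to cell number around a total
#' of `reads_per_cell` reads per cell (`count_model = "exact"` instead emits
#' exactly `round(cells * reads_per_cell)` reads per lesion, for calibration
#' tests). Each emitted base is substituted independently at `error_rate`.
#'
#' @param truth A `truth_set` from [simulate_cohort()].
#' @param error_rate Per-base substitution probability (default 1e-4).
#' @param reads_per_cell Expected reads per neoplastic cell.
#' @param include_spikein Emit normalization-control reads (default TRUE).
#' @param count_model "multinomial" (default) or "exact".
#' @param seed Optional integer seed.
#' @param design A [kras_design()].
#' @return Tibble `sample`, `seq` (one row per read).
#' @export
simulate_sample_reads <- function(truth, error_rate = 1e-4,
                                  reads_per_cell = 5e-4,
                                  include_spikein = TRUE,
                                  count_model = c("multinomial", "exact"),
                                  seed = NULL, design = kras_design()) {
  stopifnot(inherits(truth, "truth_set"), reads_per_cell > 0)
  count_model <- match.arg(count_model)

  units <- truth$tumors[, c("mouse", "variant", "barcode", "cells")]
  if (include_spikein) {
    sp <- tibble::tibble(
      mouse = unique(truth$tumors$mouse),
      variant = truth$spikein$variant,
      barcode = truth$spikein$barcode,
      cells = truth$spikein$cells
    )
    units <- dplyr::bind_rows(units, sp)
  }
  units$core <- synthesize_core(units$variant, units$barcode, design)

  with_seed_or_not(seed, {
    per_mouse <- lapply(split(units, units$mouse), function(u) {
      expected <- u$cells * reads_per_cell
      n_reads <- switch(count_model,
        exact = round(expected),
        multinomial = {
          total <- stats::rpois(1, sum(expected))
          if (total == 0L) rep(0L, nrow(u))
          else as.integer(stats::rmultinom(1, total, prob = u$cells))
        }
      )
      reads <- rep(u$core, n_reads)
      reads <- inject_errors(reads, error_rate)
      tibble::tibble(sample = u$mouse[1], seq = reads)
    })
    dplyr::bind_rows(per_mouse)
  })
}

#' Write simulated reads as FASTQ
#'
#' Sanger Phred+33 encoding with a constant quality (default Q37).
#'
#' @param reads Tibble with columns `sample`, `seq` (from
#'   [simulate_sample_reads()]).
#' @param path Output FASTQ path.
#' @param quality Constant per-base Phred quality.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = 37L) {
  qchar <- rawToChar(as.raw(quality + 33L))
  ids <- sprintf("@%s_read%06d", reads$sample, seq_len(nrow(reads)))
  quals <- vapply(nchar(reads$seq),
                  function(n) strrep(qchar, n), character(1))
  lines <- as.vector(rbind(ids, reads$seq, "+", quals))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (gz-capable).
#' @param sample Sample label to attach (default: file name).
#' @return Tibble `sample`, `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path, sample = NULL) {
  lines <- readr::read_lines(path)
  stopifnot(length(lines) %% 4L == 0L)
  idx <- seq(1L, length(lines), by = 4L)
  tibble::tibble(
    sample = sample %||% basename(path),
    id = sub("^@", "", lines[idx]),
    seq = lines[idx + 1L],
    qual = lines[idx + 3L]
  )
}

#' Simulate multi-region and metastasis samples with known lineage
#'
#' For each mouse of `truth`, every tumor is placed in one of `n_regions`
#' primary region samples; a `shared_fraction` of tumors additionally extends
#' into one adjacent region (same variant-barcode pair, smaller residual
#' mass). Each of `n_mets` metastasis samples clones the (variant, barcode)
#' of one randomly chosen primary tumor. The returned lineage table records
#' the true source links.
#'
#' @param truth A `truth_set`.
#' @param n_regions Number of primary region samples per mouse.
#' @param shared_fraction Fraction of tumors spanning two adjacent regions.
#' @param n_mets Metastasis samples per mouse.
#' @param seed Optional integer seed.
#' @return List with `calls` (tibble sample, mouse, role, variant, barcode,
#'   cells) and `lineage` (tibble mouse, met_sample, variant, barcode,
#'   source_samples).
#' @export
simulate_multiregion <- function(truth, n_regions = 3, shared_fraction = 0.2,
                                 n_mets = 2, seed = NULL) {
  stopifnot(inherits(truth, "truth_set"), n_regions >= 1,
            shared_fraction >= 0, shared_fraction <= 1)
  with_seed_or_not(seed, {
    out <- lapply(split(truth$tumors, truth$tumors$mouse), function(tt) {
      n <- nrow(tt)
      home <- sample.int(n_regions, n, replace = TRUE)
      calls <- tibble::tibble(
        sample = sprintf("%s_region%d", tt$mouse, home),
        mouse = tt$mouse, role = "primary",
        variant = tt$variant, barcode = tt$barcode, cells = tt$cells
      )
      shared <- which(stats::runif(n) < shared_fraction & rep(n_regions > 1, n))
      if (length(shared) > 0L) {
        adj <- ifelse(home[shared] == n_regions,
                      home[shared] - 1L, home[shared] + 1L)
        calls <- dplyr::bind_rows(calls, tibble::tibble(
          sample = sprintf("%s_region%d", tt$mouse[shared], adj),
          mouse = tt$mouse[shared], role = "primary",
          variant = tt$variant[shared], barcode = tt$barcode[shared],
          cells = pmax(1, round(tt$cells[shared] *
                                  stats::runif(length(shared), 0.05, 0.5)))
        ))
      }
      lineage <- NULL
      if (n_mets > 0L && n > 0L) {
        src <- sample.int(n, n_mets, replace = TRUE)
        met_sample <- sprintf("%s_met%d", tt$mouse[src], seq_len(n_mets))
        calls <- dplyr::bind_rows(calls, tibble::tibble(
          sample = met_sample, mouse = tt$mouse[src], role = "metastasis",
          variant = tt$variant[src], barcode = tt$barcode[src],
          cells = pmax(1, round(tt$cells[src] *
                                  stats::runif(n_mets, 0.01, 0.2)))
        ))
        lineage <- tibble::tibble(
          mouse = tt$mouse[src], met_sample = met_sample,
          variant = tt$variant[src], barcode = tt$barcode[src],
          source_samples = sprintf("%s_region%d", tt$mouse[src], home[src])
        )
      }
      list(calls = calls, lineage = lineage)
    })
    # a clone present twice in one sample (barcode collision within a region)
    # is one sequencing unit: aggregate
    calls <- dplyr::bind_rows(lapply(out, `[[`, "calls"))
    calls <- dplyr::summarise(
      dplyr::group_by(calls, .data$sample, .data$mouse, .data$role,
                      .data$variant, .data$barcode),
      cells = sum(.data$cells), .groups = "drop"
    )
    list(calls = calls,
         lineage = dplyr::bind_rows(lapply(out, `[[`, "lineage")))
  })
}
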