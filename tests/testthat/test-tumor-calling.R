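mutate_at_pos <- function(seq, pos, to = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
  chars[pos] <- to
  paste(chars, collapse = "")
}

test_that("denoising absorbs error-consistent neighbors and splits real ones", {
  rate <- 1e-4
  center <- clustering_seq("G12D", "CAAGGTTC")

  # neighbors at counts ~ rate * abundance / 3 are absorbed into one cluster
  neighbors <- vapply(c(5, 17, 30), function(p) mutate_at_pos(center, p),
                      character(1))
  pile <- tibble::tibble(seq = c(center, neighbors),
                         count = c(1e5, 4L, 3L, 3L))
  cl <- denoise_pileup(pile, rate)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$center, center)
  expect_equal(cl$reads, 1e5 + 10)

  # sequences >= 3 mismatches apart with large counts form separate clusters
  far <- mutate_at_pos(mutate_at_pos(mutate_at_pos(center, 2), 12), 25)
  pile2 <- tibble::tibble(seq = c(center, far), count = c(1e4, 1e4))
  cl2 <- denoise_pileup(pile2, rate)
  expect_equal(nrow(cl2), 2L)

  # a 1-mismatch neighbor far above its Poisson expectation founds a cluster
  pile3 <- tibble::tibble(seq = c(center, neighbors[1]), count = c(1e4, 1e3))
  # independent Poisson-tail oracle for the abundance p-value
  lam <- 1e4 * (rate / 3)
  p_oracle <- stats::ppois(1e3 - 1, lam, lower.tail = FALSE) /
    stats::ppois(0, lam, lower.tail = FALSE)
  expect_lt(p_oracle, 0.01)
  cl3 <- denoise_pileup(pile3, rate)
  expect_equal(nrow(cl3), 2L)
  expect_setequal(cl3$reads, c(1e4, 1e3))
})

test_that("denoising conserves reads and handles the zero-error limit", {
  set.seed(31)
  alleles <- random_alleles(30)
  pile <- tally_pileup(rep(clustering_seq(alleles$variant, alleles$barcode),
                           times = sample(1:50, 30, replace = TRUE)))
  for (rate in c(0, 1e-4)) {
    cl <- denoise_pileup(pile, rate)
    expect_equal(sum(cl$reads), sum(pile$count))
  }
  # zero error rate: every distinct sequence is its own cluster
  cl0 <- denoise_pileup(pile, 0)
  expect_equal(nrow(cl0), nrow(pile))
})

test_that("shadow removal drops only 1-mismatch calls 10^4-fold smaller", {
  center <- clustering_seq("G12V", "AGGAGTGA")
  near <- mutate_at_pos(center, 10)
  far2 <- mutate_at_pos(near, 20)

  # 10 reads at distance 1 from a 1e6-read cluster: removed
  cl <- tibble::tibble(center = c(center, near), reads = c(1e6, 10))
  out <- remove_shadows(cl)
  expect_equal(out$center, center)
  expect_equal(attr(out, "removed_fraction"), 0.5)

  # ratio 1e3 < 1e4: kept
  cl2 <- tibble::tibble(center = c(center, near), reads = c(1e4, 10))
  expect_equal(nrow(remove_shadows(cl2)), 2L)

  # distance 2 from a huge cluster: kept
  cl3 <- tibble::tibble(center = c(center, far2), reads = c(1e9, 10))
  expect_equal(nrow(remove_shadows(cl3)), 2L)
})

test_that("spike-in normalization converts reads to absolute cells", {
  sp <- spikein_allele()
  calls <- tibble::tibble(
    sample = "s1",
    variant = c("G12D", "G12C", sp$variant),
    barcode = c("AAGTGTGA", "CCGTGTGA", sp$barcode),
    reads = c(1000, 2000, 1000)
  )
  out <- normalize_to_spikein(calls)
  expect_equal(out$cells[1], 5e5)
  expect_equal(out$cells[2], 1e6)
  expect_true(out$is_spikein[3])
  expect_error(normalize_to_spikein(calls[1:2, ]), "no spike-in")
})

test_that("size cutoffs follow the lung and pancreas rules", {
  calls <- tibble::tibble(
    sample = "s1", variant = c("G12D", "G12R"),
    barcode = c("AAGTGTGA", "CCGTGTGA"),
    reads = c(10, 10), cells = c(100001, 100000), is_spikein = FALSE
  )
  cut <- apply_size_cutoff(calls, "lung")
  expect_equal(cut$kept$variant, "G12D")    # strictly greater than 1e5
  expect_equal(cut$dropped$variant, "G12R")

  pan <- tibble::tibble(
    sample = "s1",
    variant = c("WT", "WT", "G12D", "G12V"),
    barcode = c("AAGTGTGA", "CCGTGTGA", "GAGTGTGA", "TAGTGTGA"),
    reads = c(500, 100, 1001, 999)
  )
  cutp <- apply_size_cutoff(pan, "pancreas")
  expect_equal(cutp$kept$variant, "G12D")   # > 2 x max WT (1000)
  # a sample without WT gets threshold 0 with a warning
  expect_warning(
    cut0 <- apply_size_cutoff(pan[3:4, ], "pancreas"), "no WT call")
  expect_equal(nrow(cut0$kept), 2L)

  empty <- calls[0, ]
  expect_equal(nrow(apply_size_cutoff(empty, "lung")$kept), 0L)
})

test_that("exact-count simulation is recovered exactly after calling", {
  pool <- simulate_plasmid_pool(depth = 5e4, seed = 301)
  truth <- simulate_cohort(pool, n_mice = 1, mean_tumors = 50, seed = 302)
  # snap sizes to whole read units so cells -> reads -> cells is lossless
  truth$tumors$cells <- pmax(1, round(truth$tumors$cells / 1000)) * 1000
  reads <- simulate_sample_reads(truth, error_rate = 0, reads_per_cell = 1e-3,
                                 count_model = "exact", seed = 303)
  pile <- tally_pileup(filter_and_trim(reads$seq)$seq)
  calls <- call_tumors(pile, sample = "mouse_01")
  tumors <- calls[!calls$is_spikein, ]

  # truth aggregated by pair (same-barcode tumors merge into one lesion)
  agg <- dplyr::summarise(
    dplyr::group_by(truth$tumors, .data$variant, .data$barcode),
    cells = sum(.data$cells), .groups = "drop")
  got <- dplyr::arrange(tumors[, c("variant", "barcode", "cells")],
                        .data$variant, .data$barcode)
  want <- dplyr::arrange(agg, .data$variant, .data$barcode)
  expect_equal(got$variant, want$variant)
  expect_equal(got$barcode, want$barcode)
  expect_equal(got$cells, want$cells)
})

test_that("replicate concordance is high for technical replicates", {
  pool <- simulate_plasmid_pool(depth = 5e4, seed = 304)
  truth <- simulate_cohort(pool, n_mice = 1, mean_tumors = 80, seed = 305)
  call_rep <- function(seed) {
    reads <- simulate_sample_reads(truth, error_rate = 1e-4,
                                   reads_per_cell = 2e-3, seed = seed)
    pile <- tally_pileup(filter_and_trim(reads$seq)$seq)
    calls <- call_tumors(pile, sample = "rep")
    apply_size_cutoff(calls, "lung")$kept
  }
  a <- call_rep(306)
  b <- call_rep(307)
  res <- replicate_concordance(a, b)
  expect_gte(res$n_shared, 3L)
  expect_gt(res$r_squared, 0.99)

  expect_equal(suppressWarnings(replicate_concordance(a, a))$r_squared, 1)
  expect_error(replicate_concordance(a[1:2, ], b[1:2, ]), "at least 3")
})
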