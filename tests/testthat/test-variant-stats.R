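# independent oracle: two-sided Fisher p by full hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("variant representation trims pool-wide abundant barcodes", {
  d <- kras_design()
  set.seed(501)
  classes <- allele_classes(d)$variant
  pool <- tibble::tibble(
    variant = rep(classes, each = 100),
    barcode = sample(enumerate_barcodes(d), 1300),  # distinct barcodes
    reads = 10L
  )
  pool$reads <- ifelse(pool$variant == "WT", 40L, 10L)
  rep_tbl <- variant_representation(pool, trim_percentile = 98)
  expect_equal(sum(rep_tbl$fraction), 1)
  expect_equal(rep_tbl$fraction[rep_tbl$variant == "WT"], 4 / 16,
               tolerance = 1e-12)

  # a jackpot barcode holding half the reads is excluded by the trim
  pool2 <- pool
  pool2$reads[1] <- sum(pool$reads)
  rep2 <- variant_representation(pool2, trim_percentile = 98)
  expect_equal(rep2$fraction, rep_tbl$fraction, tolerance = 0.05)
})

test_that("normalized tumor numbers are WT-scaled and rescaling-invariant", {
  counts <- tibble::tibble(variant = c("G12D", "WT"), n = c(40L, 4L))
  rep_tbl <- tibble::tibble(variant = c("G12D", "WT"),
                            reads = c(100L, 400L),
                            fraction = c(1 / 16, 4 / 16))
  out <- normalized_tumor_number(counts, rep_tbl)
  expect_equal(out$relative[out$variant == "G12D"], 40)
  expect_equal(out$relative[out$variant == "WT"], 1)

  # counts proportional to representation: every relative value is 1
  counts2 <- tibble::tibble(variant = c("G12D", "WT"), n = c(10L, 40L))
  out2 <- normalized_tumor_number(counts2, rep_tbl)
  expect_equal(out2$relative, c(1, 1))

  # invariant to uniform rescaling of the representations
  rep_scaled <- rep_tbl
  rep_scaled$fraction <- rep_scaled$fraction * 5
  out3 <- normalized_tumor_number(counts, rep_scaled)
  expect_equal(out3$relative, out$relative)

  # structural zero: no WT scaling, flagged
  counts0 <- tibble::tibble(variant = c("G12D", "WT"), n = c(40L, 0L))
  out0 <- normalized_tumor_number(counts0, rep_tbl)
  expect_false(any(out0$wt_scaled))
})

test_that("Fisher test agrees with hypergeometric enumeration", {
  expect_equal(fisher_vs_reference(10, 10, 1000, 1000)$p_value, 1)
  # random tables with margins up to 30 against the enumeration oracle
  set.seed(502)
  for (i in 1:50) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    got <- fisher_vs_reference(a, b, c, d, n_variants = 1)$p_value
    want <- if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) 1 else
      fisher_oracle(a, b, c, d)
    expect_equal(got, want, tolerance = 1e-8,
                 label = sprintf("table [%d %d; %d %d]", a, b, c, d))
  }
  # Bonferroni caps at 1
  expect_lte(fisher_vs_reference(5, 0, 100, 100, n_variants = 12)$p_adjusted, 1)
})

test_that("structural-zero test is the exact binomial tail", {
  expect_equal(structural_zero_test(0, 0.1, 0.1)$p_value, 1)
  res <- structural_zero_test(10, 0.25, 0.25)
  expect_equal(res$p_one_sided, 0.5^10)
  expect_equal(res$p_value, 2 * 0.5^10)
  # Monte-Carlo null oracle: probability of zero reference draws
  set.seed(503)
  n_mc <- 1e5
  p_ref <- 0.25 / (0.25 + 0.75)
  mc <- mean(stats::rbinom(n_mc, 10, p_ref) == 0)
  exact <- structural_zero_test(10, 0.75, 0.25)$p_one_sided
  se <- sqrt(exact * (1 - exact) / n_mc)
  expect_lt(abs(mc - exact), 3 * se)
})

test_that("genotype spectrum chi-square matches the textbook formula", {
  even <- matrix(c(10, 10, 20, 20), 2)
  res <- genotype_spectrum_chisq(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  tbl <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  res2 <- genotype_spectrum_chisq(tbl)
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res2$df, 1)

  # invariant under column permutation
  res3 <- genotype_spectrum_chisq(tbl[, 2:1])
  expect_equal(res3$statistic, res2$statistic)

  expect_warning(genotype_spectrum_chisq(matrix(c(1, 0, 0, 1), 2)),
                 "expected cell")
})

test_that("bootstrap intervals contain the point estimate and are seeded", {
  set.seed(504)
  calls <- tibble::tibble(
    variant = sample(c("G12D", "G12V", "WT"), 200, replace = TRUE,
                     prob = c(0.6, 0.3, 0.1)))
  rep_tbl <- tibble::tibble(variant = c("G12D", "G12V", "WT"),
                            reads = c(100L, 100L, 400L),
                            fraction = c(1 / 6, 1 / 6, 4 / 6))
  ci <- bootstrap_ci(calls, rep_tbl, n_boot = 500, seed = 505)
  expect_true(all(ci$ci_lo <= ci$relative & ci$relative <= ci$ci_hi))
  expect_identical(ci, bootstrap_ci(calls, rep_tbl, n_boot = 500, seed = 505))

  # width shrinks roughly as 1/sqrt(n) when the tumor count grows 4x
  calls4 <- tibble::tibble(variant = rep(calls$variant, 4))
  ci4 <- bootstrap_ci(calls4, rep_tbl, n_boot = 500, seed = 506)
  w <- ci$ci_hi - ci$ci_lo
  w4 <- ci4$ci_hi - ci4$ci_lo
  ratio <- (w4 / w)[w > 0]
  expect_true(all(ratio > 0.25 & ratio < 0.85))
})

test_that("library-vs-observed allele correlation behaves as a correlation", {
  x <- c(0.25, 0.1, 0.2, 0.45)
  expect_equal(hdr_bias_correlation(x, x)$r, 1)
  expect_lt(hdr_bias_correlation(x, rev(sort(x))[rank(x)])$r, 0)
  expect_error(hdr_bias_correlation(rep(0.25, 4), x), "zero variance")

  # unbiased HDR: multinomial resampling of the pool at 1e4 events
  set.seed(507)
  p <- c(4, rep(1, 12)) / 16
  obs <- as.vector(stats::rmultinom(1, 1e4, p)) / 1e4
  expect_gt(hdr_bias_correlation(p, obs)$r_squared, 0.9)
})

test_that("null simulations hold the nominal type-I error", {
  # counts drawn proportional to representation: uncorrected Fisher p < 0.05
  # for about 5% of variants
  set.seed(508)
  rep_reads <- c(WT = 4000L, stats::setNames(rep(1000L, 12),
                                             enumerate_variants()$variant))
  n_sims <- 150
  n_tumors <- 400
  hits <- 0; total <- 0
  for (s in seq_len(n_sims)) {
    cnt <- as.vector(stats::rmultinom(1, n_tumors, rep_reads / sum(rep_reads)))
    names(cnt) <- names(rep_reads)
    for (v in setdiff(names(cnt), "WT")) {
      p <- fisher_vs_reference(cnt[[v]], cnt[["WT"]],
                               rep_reads[[v]], rep_reads[["WT"]],
                               n_variants = 1)$p_value
      hits <- hits + (p < 0.05)
      total <- total + 1
    }
  }
  rate <- hits / total
  # Fisher is conservative for discrete tables, so the rate may fall below
  # nominal, but must never exceed the binomial upper band around 0.05
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})
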