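# Chi-squared testing, p-value bounds, and multiple-testing correction.

test_that("goodness-of-fit chi-squared reproduces hand-computed tables", {
  # 44 of 88 alleles rare against a population frequency of 8%
  cat1 <- makeCatalogue("6", 100L, rare_freq = 0.08)
  f <- data.frame(chrom = "6", pos = 100L, snp_id = "rs1", ref_allele = "A",
                  rare_allele = "G", source = "test", rare_count = 44L,
                  allele_total = 88L, n_unknown_alleles = 0L,
                  freq = 0.5, freq_lower = 0.5, freq_upper = 0.5,
                  untestable = FALSE)
  res <- chiSquareVsCatalogue(f, cat1)
  expect_equal(res$chi2, (44 - 7.04)^2 / 7.04 + (44 - 80.96)^2 / 80.96)
  expect_equal(res$chi2, 210.91, tolerance = 1e-4)
  expect_equal(res$p_raw, stats::pchisq(res$chi2, 1, lower.tail = FALSE))
  expect_lt(res$p_raw, 2e-47)       # magnitude ~1e-47
  expect_gt(res$p_raw, 2e-48)
  expect_equal(res$direction, "enriched")

  # observed equals expected: chi2 = 0, p = 1
  f$rare_count <- 16L; f$allele_total <- 200L; f$freq <- 0.08
  res0 <- chiSquareVsCatalogue(f, cat1)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p_raw, 1)

  # total depletion against q = 0.5: chi2 = (0-100)^2/100 + (200-100)^2/100
  cat50 <- makeCatalogue("6", 100L, rare_freq = 0.5)
  f$rare_count <- 0L; f$freq <- 0
  res2 <- chiSquareVsCatalogue(f, cat50)
  expect_equal(res2$chi2, 200)
  expect_equal(res2$direction, "depleted")
})

test_that("vectorised chi-squared agrees with the brute-force formula and chisq.test", {
  set.seed(7)
  n <- 500
  total <- sample(20:400, n, replace = TRUE)
  rare <- vapply(total, function(t) sample.int(t + 1L, 1L) - 1L, integer(1))
  q <- runif(n, 0.01, 0.49)
  cat1 <- makeCatalogue("1", (1:n) * 10L, rare_freq = round(q, 6))
  q <- catalogueData(cat1)$rare_freq
  f <- data.frame(chrom = "1", pos = (1:n) * 10L, snp_id = ".",
                  ref_allele = "A", rare_allele = "G", source = "t",
                  rare_count = rare, allele_total = total,
                  n_unknown_alleles = 0L, freq = rare / total,
                  freq_lower = rare / total, freq_upper = rare / total,
                  untestable = FALSE)
  res <- chiSquareVsCatalogue(f, cat1)
  brute <- mapply(oracleChi2, rare, total, q)
  expect_true(all(abs(res$chi2 - brute) < 1e-10))

  # spot-check against stats::chisq.test on a handful of tables
  for (i in sample(n, 5)) {
    ct <- suppressWarnings(
      stats::chisq.test(c(rare[i], total[i] - rare[i]),
                        p = c(q[i], 1 - q[i]), correct = FALSE))
    expect_equal(res$chi2[i], unname(ct$statistic))
    expect_equal(res$p_raw[i], unname(ct$p.value))
  }
})

test_that("two-sample mode matches chisq.test and converges to goodness-of-fit", {
  cat1 <- makeCatalogue("1", 100L, rare_freq = 0.08, allele_number = 1000)
  f <- data.frame(chrom = "1", pos = 100L, snp_id = ".", ref_allele = "A",
                  rare_allele = "G", source = "t", rare_count = 44L,
                  allele_total = 88L, n_unknown_alleles = 0L, freq = 0.5,
                  freq_lower = 0.5, freq_upper = 0.5, untestable = FALSE)
  res <- chiSquareVsCatalogue(f, cat1, mode = "two_sample")
  tab <- matrix(c(44, 44, 80, 920), 2, byrow = TRUE)  # 0.08 * 1000 = 80
  ct <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(res$chi2, unname(ct$statistic))
  expect_equal(res$p_raw, unname(ct$p.value))

  # catalogue allele number -> infinity recovers the goodness-of-fit p
  catBig <- makeCatalogue("1", 100L, rare_freq = 0.08, allele_number = 1e6)
  pTwo <- chiSquareVsCatalogue(f, catBig, mode = "two_sample")$p_raw
  pGof <- chiSquareVsCatalogue(f, cat1)$p_raw
  expect_equal(log(pTwo), log(pGof), tolerance = 0.01)
})

test_that("untestable and low-expected situations are flagged, not silently dropped", {
  cat0 <- makeCatalogue("1", c(100L, 200L), rare_freq = c(0, 0.001))
  f <- data.frame(chrom = "1", pos = c(100L, 200L), snp_id = ".",
                  ref_allele = "A", rare_allele = "G", source = "t",
                  rare_count = c(5L, 5L), allele_total = c(100L, 100L),
                  n_unknown_alleles = 0L, freq = 0.05, freq_lower = 0.05,
                  freq_upper = 0.05, untestable = FALSE)
  res <- chiSquareVsCatalogue(f, cat0)
  expect_true(res$untestable[1])        # q = 0 cannot be tested
  expect_true(is.na(res$p_raw[1]))
  expect_false(res$untestable[2])
  expect_true(res$low_expected[2])      # expected rare count 0.1 < 1
  expect_false(is.na(res$p_raw[2]))
})

test_that("Bonferroni and BH corrections follow the hand-executed procedures", {
  cat1 <- makeCatalogue("1", c(10L, 20L, 30L), rare_freq = rep(0.1, 3))
  res <- data.frame(chrom = "1", pos = c(10L, 20L, 30L), snp_id = ".",
                    rare_allele = "G", source = "t", rare_count = 1L,
                    allele_total = 10L, n_unknown_alleles = 0L, freq = 0.1,
                    catalogue_freq = 0.1, chi2 = 1,
                    p_raw = c(0.001, 0.002, 0.03),
                    direction = "enriched", low_expected = FALSE,
                    untestable = FALSE, mode = "goodness_of_fit")
  out <- correctPvalues(res, alpha = 0.01)
  expect_equal(out$m, rep(3L, 3))
  expect_equal(out$p_bonferroni, c(0.003, 0.006, 0.09))
  expect_equal(out$q_fdr, c(0.003, 0.003, 0.03))   # step-up BH
  expect_equal(out$significant, c(TRUE, TRUE, FALSE))

  # ceiling at 1
  res$p_raw <- c(1.0, 0.5, 0.9)
  out2 <- correctPvalues(res)
  expect_equal(max(out2$p_bonferroni), 1.0)
  expect_equal(out2$q_fdr[out2$p_raw == 1.0], 1.0)

  # empty input stays empty
  expect_equal(nrow(correctPvalues(res[0, , drop = FALSE])), 0L)
})

test_that("a genome-scale correction denominator preserves extreme significance", {
  # the 44-carrier example corrected over 121,000 SNPs stays far below 1e-8
  p <- stats::pchisq(oracleChi2(44, 88, 0.08), 1, lower.tail = FALSE)
  bonf <- min(1, 121000 * p)
  expect_lt(bonf, 1e-8)
  expect_equal(bonf, 1.05e-42, tolerance = 0.01)
})

test_that("BH q-values are monotone and Bonferroni calls are a subset of BH calls", {
  set.seed(11)
  n <- 200
  cat1 <- makeCatalogue("1", (1:n) * 10L, rare_freq = rep(0.1, n))
  res <- data.frame(chrom = "1", pos = (1:n) * 10L, snp_id = ".",
                    rare_allele = "G", source = "t", rare_count = 1L,
                    allele_total = 10L, n_unknown_alleles = 0L, freq = 0.1,
                    catalogue_freq = 0.1, chi2 = 1,
                    p_raw = runif(n)^3, direction = "enriched",
                    low_expected = FALSE, untestable = FALSE,
                    mode = "goodness_of_fit")
  out <- correctPvalues(res, alpha = 0.05)
  expect_true(!is.unsorted(out$p_raw))           # sorted output
  expect_true(!is.unsorted(out$q_fdr))           # BH monotone in that order
  expect_true(all(out$q_fdr >= out$p_raw))
  expect_true(all(out$p_bonferroni >= out$p_raw))
  expect_true(all(which(out$p_bonferroni < 0.05) %in%
                    which(out$q_fdr < 0.05)))
})

test_that("p-value bounds at the extreme allocations follow the frequency bounds", {
  cat1 <- makeCatalogue("1", 100L, rare_freq = 0.1)
  # 3 rare of 16 observed, 4 unknown alleles: bounds at 3/20 and 7/20
  f <- data.frame(chrom = "1", pos = 100L, snp_id = ".", ref_allele = "A",
                  rare_allele = "G", source = "t", rare_count = 3L,
                  allele_total = 16L, n_unknown_alleles = 4L,
                  freq = 3 / 16, freq_lower = 3 / 20, freq_upper = 7 / 20,
                  untestable = FALSE)
  b <- boundPvalues(f, cat1)
  pAt <- function(r) stats::pchisq(oracleChi2(r, 20, 0.1), 1,
                                   lower.tail = FALSE)
  expect_equal(b$p_raw_lower, pAt(3))
  expect_equal(b$p_raw_upper, pAt(7))

  # zero unknowns: a degenerate range, all four values coincide
  f0 <- f; f0$n_unknown_alleles <- 0L; f0$allele_total <- 20L
  b0 <- boundPvalues(f0, cat1)
  expect_equal(b0$p_raw_lower, b0$p_raw_upper)
  expect_equal(b0$p_range_min, b0$p_range_max)
  expect_equal(b0$p_raw_lower, pAt(3))

  # when the observed frequency already sits at q, pushing all unknowns to
  # rare moves the cohort away from expectation: that allocation's p < 1
  f1 <- f; f1$rare_count <- 2L; f1$allele_total <- 20L
  f1$n_unknown_alleles <- 10L; f1$freq <- 0.1
  b1 <- boundPvalues(f1, cat1)
  expect_lt(b1$p_raw_upper, 1)
})

test_that("the reported p range brackets every allocation of unknown alleles", {
  set.seed(3)
  for (i in 1:200) {
    t <- sample(10:60, 1)
    r <- sample.int(t + 1L, 1L) - 1L
    u <- sample.int(6L, 1L)
    q <- runif(1, 0.02, 0.48)
    cat1 <- makeCatalogue("1", 100L, rare_freq = round(q, 6))
    q <- catalogueData(cat1)$rare_freq
    f <- data.frame(chrom = "1", pos = 100L, snp_id = ".", ref_allele = "A",
                    rare_allele = "G", source = "t", rare_count = r,
                    allele_total = t, n_unknown_alleles = u,
                    freq = r / t, freq_lower = r / (t + u),
                    freq_upper = (r + u) / (t + u), untestable = FALSE)
    b <- boundPvalues(f, cat1)
    # exhaustive brute force over every integer allocation
    allP <- vapply(0:u, function(x)
      stats::pchisq(oracleChi2(r + x, t + u, q), 1, lower.tail = FALSE),
      numeric(1))
    expect_true(all(allP >= b$p_range_min - 1e-12))
    expect_true(all(allP <= b$p_range_max + 1e-12))
    # and the range is tight: both ends attained
    expect_equal(min(allP), b$p_range_min)
    expect_equal(max(allP), b$p_range_max)
  }
})
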