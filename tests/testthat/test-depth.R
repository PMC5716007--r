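# Depth lookup, the 20x call filter, and the exon/gene coverage census.

test_that("site depth lookup returns table values and NA for absent positions", {
  dt <- readDepthTable(writeDepthTsv("1", c(500L, 600L), c(37L, 19L)))
  expect_equal(siteDepth(dt, "1", 500L), 37)
  expect_equal(siteDepth(dt, "1", 600L), 19)
  expect_true(is.na(siteDepth(dt, "1", 700L)))
  # chr-prefix insensitive
  expect_equal(siteDepth(dt, "chr1", 500L), 37)
})

depthFixtureCohort <- function(depths, gts = c("0/1", "0/1", "0/1")) {
  # three catalogue SNPs, one sample, explicit depths per site
  cat1 <- makeCatalogue("1", c(100L, 200L, 300L), rare_freq = rep(0.1, 3))
  recs <- data.frame(chrom = "1", pos = c(100L, 200L, 300L), id = ".",
                     ref = "A", alt = "G", gt = gts)
  vcf <- writeSampleVcf(recs[!is.na(recs$gt), , drop = FALSE])
  dp <- writeDepthTsv("1", c(100L, 200L, 300L), depths)
  man <- data.frame(sample_id = "s1", vcf_path = vcf, depth_path = dp,
                    sex = "F")
  readCohort(man, cat1, inferSexes = FALSE)
}

test_that("calls below the depth cutoff are demoted to unknown", {
  cohort <- depthFixtureCohort(depths = c(19L, 20L, 50L))
  suppressMessages(filtered <- applyDepthFilter(cohort, cutoff = 20))
  st <- callStatus(filtered)[, 1]
  expect_equal(unname(st), c("unknown", "called", "called"))
  expect_true(is.na(rareCounts(filtered)[1, 1]))
  # depth exactly at the cutoff passes
  expect_equal(unname(rareCounts(filtered)[2, 1]), 1L)
})

test_that("absent sites are resolved by depth evidence in either direction", {
  cat1 <- makeCatalogue("1", c(100L, 200L), rare_freq = c(0.1, 0.1))
  vcf <- writeSampleVcf(data.frame(chrom = character(0), pos = integer(0),
                                   id = character(0), ref = character(0),
                                   alt = character(0), gt = character(0)))
  dp <- writeDepthTsv("1", c(100L, 200L), c(35L, 0L))
  man <- data.frame(sample_id = "s1", vcf_path = vcf, depth_path = dp,
                    sex = "F")
  # start from the conservative policy: everything absent is unknown
  cohort <- readCohort(man, cat1, absentPolicy = "unknown",
                       inferSexes = FALSE)
  filtered <- applyDepthFilter(cohort, cutoff = 20)
  st <- callStatus(filtered)[, 1]
  expect_equal(unname(st), c("ref_assumed", "unknown"))  # 35x covered vs 0x
  expect_equal(unname(rareCounts(filtered)[1, 1]), 0L)

  # and an optimistic ref_assumed call with no read support is demoted
  cohort2 <- readCohort(man, cat1, absentPolicy = "ref_assumed",
                        inferSexes = FALSE)
  suppressMessages(filtered2 <- applyDepthFilter(cohort2, cutoff = 20))
  expect_equal(unname(callStatus(filtered2)[, 1]),
               c("ref_assumed", "unknown"))
})

test_that("the depth filter is idempotent and never raises rare counts", {
  cohort <- depthFixtureCohort(depths = c(5L, 25L, 60L))
  suppressMessages(once <- applyDepthFilter(cohort, cutoff = 20))
  suppressMessages(twice <- applyDepthFilter(once, cutoff = 20))
  expect_identical(callStatus(once), callStatus(twice))
  expect_identical(rareCounts(once), rareCounts(twice))
  before <- cohortFrequencies(cohort)$rare_count
  after <- cohortFrequencies(once)$rare_count
  expect_true(all(after <= before))
})

test_that("exon census matches direct arithmetic on constant and mixed depth", {
  bed <- tempfile(fileext = ".bed")
  # one 10-base exon [0,10) and one mixed exon [100,110)
  writeLines(c("1\t0\t10\tGENEA\tGENEA_ex1",
               "1\t100\t110\tGENEB\tGENEB_ex1"), bed)
  dp <- writeDepthTsv("1", c(1:10, 101:110),
                      c(rep(30L, 10), rep(10L, 5), rep(30L, 5)))
  census <- exonCoverageCensus(c(s1 = dp), bed, cutoff = 20)
  ex <- census$exons
  expect_equal(ex$mean_depth[ex$gene == "GENEA"], 30)
  expect_equal(ex$fraction_ge_cutoff[ex$gene == "GENEA"], 1.0)
  expect_equal(ex$mean_depth[ex$gene == "GENEB"], 20)
  expect_equal(ex$fraction_ge_cutoff[ex$gene == "GENEB"], 0.5)
})

test_that("census mean equals a brute-force per-base average across samples", {
  set.seed(42)
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t10\t35\tGENEA\tGENEA_ex1",
               "1\t50\t70\tGENEA\tGENEA_ex2",
               "1\t90\t97\tGENEB\tGENEB_ex1"), bed)
  positions <- 1:120
  d1 <- sample(0:60, 120, replace = TRUE)
  d2 <- sample(0:60, 120, replace = TRUE)
  p1 <- writeDepthTsv("1", positions, d1)
  p2 <- writeDepthTsv("1", positions, d2)
  census <- exonCoverageCensus(c(a = p1, b = p2), bed, cutoff = 20)
  bruteMean <- function(lo, hi) mean(c(d1[lo:hi], d2[lo:hi]))
  expect_equal(census$exons$mean_depth,
               c(bruteMean(11, 35), bruteMean(51, 70), bruteMean(91, 97)))
  geneA <- census$genes[census$genes$gene == "GENEA", ]
  expect_equal(geneA$mean_depth, mean(c(d1[c(11:35, 51:70)],
                                        d2[c(11:35, 51:70)])))
})

test_that("overlapping exons of a gene are counted once and >19 is strict", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t0\t10\tGENEA\tGENEA_ex1",
               "1\t5\t15\tGENEA\tGENEA_ex2"), bed)   # bases 6-10 shared
  dp <- writeDepthTsv("1", 1:15, c(rep(10L, 5), rep(23L, 10)))
  census <- exonCoverageCensus(c(s1 = dp), bed, cutoff = 20)
  g <- census$genes
  expect_equal(g$n_bases, 15L)                        # deduplicated union
  expect_equal(g$mean_depth, mean(c(rep(10, 5), rep(23, 10))))  # 18.667
  expect_false(g$adequately_covered)                  # 18.667 <= 19

  dp2 <- writeDepthTsv("1", 1:15, rep(19L, 15))
  g2 <- exonCoverageCensus(c(s1 = dp2), bed, cutoff = 20)$genes
  expect_equal(g2$mean_depth, 19)
  expect_false(g2$adequately_covered)                 # exactly 19 fails
  dp3 <- writeDepthTsv("1", 1:15, rep(20L, 15))
  expect_true(exonCoverageCensus(c(s1 = dp3), bed,
                                 cutoff = 20)$genes$adequately_covered)
})
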