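# Per-sample VCF aggregation, absent-site policy, sex inference and the
# declared-count check.

test_that("genotypes at catalogue SNPs map to rare-allele counts", {
  cat1 <- makeCatalogue("1", c(100L, 200L, 300L, 400L, 500L),
                        rare_freq = rep(0.1, 5))
  vcf <- writeSampleVcf(data.frame(
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    id = ".", ref = "A",
    alt = c("G", "G", "G", "G"),
    gt = c("0/1", "1/1", "./1", "./.")))
  man <- data.frame(sample_id = "s1", vcf_path = vcf, sex = "F")
  cohort <- readCohort(man, cat1, inferSexes = FALSE)
  rc <- rareCounts(cohort)[, 1]
  st <- callStatus(cohort)[, 1]
  expect_equal(unname(rc[1]), 1L)               # 0/1 het
  expect_equal(unname(st[1]), "called")
  expect_equal(unname(rc[2]), 2L)               # 1/1 hom rare
  expect_equal(unname(st[3]), "unknown")        # half-call
  expect_equal(unname(st[4]), "unknown")        # missing GT
  expect_equal(unname(st[5]), "ref_assumed")    # absent, default policy
  expect_equal(unname(rc[5]), 0L)
})

test_that("absent-site policy is configurable", {
  cat1 <- makeCatalogue("1", 100L, rare_freq = 0.1)
  vcf <- writeSampleVcf(data.frame(chrom = character(0), pos = integer(0),
                                   id = character(0), ref = character(0),
                                   alt = character(0), gt = character(0)))
  man <- data.frame(sample_id = "s1", vcf_path = vcf, sex = "F")
  st1 <- callStatus(readCohort(man, cat1, inferSexes = FALSE))[1, 1]
  st2 <- callStatus(readCohort(man, cat1, absentPolicy = "unknown",
                               inferSexes = FALSE))[1, 1]
  expect_equal(unname(st1), "ref_assumed")
  expect_equal(unname(st2), "unknown")
})

test_that("records carrying non-catalogue alternate alleles contribute their non-rare alleles", {
  cat1 <- makeCatalogue("1", c(100L, 200L), rare_freq = c(0.1, 0.1))
  # at pos 100 the sample carries a different ALT (T, not the catalogue G);
  # at pos 200 a triallelic record where allele 2 is the catalogue allele
  vcf <- writeSampleVcf(data.frame(chrom = "1", pos = c(100L, 200L),
                                   id = ".", ref = "A",
                                   alt = c("T", "T,G"),
                                   gt = c("0/1", "1/2")))
  man <- data.frame(sample_id = "s1", vcf_path = vcf, sex = "F")
  cohort <- readCohort(man, cat1, inferSexes = FALSE)
  expect_equal(unname(rareCounts(cohort)[, 1]), c(0L, 1L))
  expect_equal(unname(callStatus(cohort)[, 1]), c("called", "called"))
})

test_that("out-of-range GT indices skip the record with a warning", {
  cat1 <- makeCatalogue("1", 100L, rare_freq = 0.1)
  vcf <- writeSampleVcf(data.frame(chrom = "1", pos = 100L, id = ".",
                                   ref = "A", alt = "G", gt = "0/3"))
  man <- data.frame(sample_id = "s1", vcf_path = vcf, sex = "F")
  expect_warning(cohort <- readCohort(man, cat1, inferSexes = FALSE),
                 "skipped")
  # skipped record falls back to the absent policy
  expect_equal(unname(callStatus(cohort)[1, 1]), "ref_assumed")
})

test_that("every (sample, catalogue SNP) pair yields exactly one call", {
  fx <- makeFixture(fixtureSpec(nSamples = 6, nMales = 3, nSnps = 40,
                                propX = 0.25, seed = 11), tempfile())
  cat1 <- readCatalogue(fx$catalogue, source = "popA")
  cohort <- readCohort(fx$manifest, cat1)
  expect_equal(dim(rareCounts(cohort)),
               c(length(cat1), nrow(fx$manifest)))
  expect_false(any(is.na(callStatus(cohort))))
  expect_equal(length(callStatus(cohort)),
               length(cat1) * nrow(fx$manifest))
})

test_that("an unreadable VCF is a hard error naming the sample", {
  cat1 <- makeCatalogue("1", 100L, rare_freq = 0.1)
  man <- data.frame(sample_id = "badsample", vcf_path = "/nonexistent.vcf",
                    sex = "F")
  expect_error(readCohort(man, cat1), "badsample")
})

test_that("X heterozygosity separates the sexes at the documented thresholds", {
  # 200 non-PAR X SNPs, outside PAR1 (ends 2,699,520)
  cat1 <- makeCatalogue("X", 3e6L + (1:200) * 1000L, rare_freq = rep(0.3, 200))
  hetFrac <- function(nHet) {
    rc <- matrix(0L, 200, 1)
    rc[seq_len(nHet), 1] <- 1L
    het <- matrix(FALSE, 200, 1); het[seq_len(nHet), 1] <- TRUE
    cohort <- makeCohortCalls(cat1, rc, status = "called", het = het,
                              sex = "unknown")
    unname(inferredSex(inferSex(cohort)))
  }
  expect_equal(hetFrac(0), "male")      # h = 0
  expect_equal(hetFrac(60), "female")   # h = 0.30 > 0.20
  expect_equal(hetFrac(20), "ambiguous")# h = 0.10 between the thresholds
})

test_that("sex inference needs a minimum number of X calls", {
  cat1 <- makeCatalogue("X", 3e6L + (1:30) * 1000L, rare_freq = rep(0.3, 30))
  cohort <- makeCohortCalls(cat1, matrix(0L, 30, 1), status = "called",
                            het = matrix(FALSE, 30, 1), sex = "unknown")
  expect_equal(unname(inferredSex(inferSex(cohort))), "ambiguous")
  expect_equal(unname(inferredSex(inferSex(cohort, minCalls = 10))), "male")
})

test_that("PAR X SNPs are excluded from sex inference", {
  # all SNPs inside PAR1: even 0 heterozygosity must not call a sex
  cat1 <- makeCatalogue("X", (1:100) * 100L + 60000L,
                        rare_freq = rep(0.3, 100))
  cohort <- makeCohortCalls(cat1, matrix(0L, 100, 1), status = "called",
                            het = matrix(FALSE, 100, 1), sex = "unknown")
  expect_equal(unname(inferredSex(inferSex(cohort, minCalls = 10))),
               "ambiguous")
})

test_that("sex inference on a generated cohort recovers every known sex", {
  fx <- makeFixture(fixtureSpec(nSamples = 8, nMales = 3, nSnps = 300,
                                propX = 0.4, seed = 5), tempfile())
  cat1 <- readCatalogue(fx$catalogue, source = "popA")
  cohort <- readCohort(fx$manifest, cat1, inferSexes = TRUE, minCalls = 20)
  inferred <- unname(inferredSex(cohort))
  declared <- ifelse(fx$manifest$sex == "M", "male", "female")
  expect_equal(inferred, declared)
})

test_that("declared-count verification reports agreement and mismatches", {
  fx <- makeFixture(fixtureSpec(nSamples = 5, nMales = 3, nSnps = 250,
                                propX = 0.4, seed = 9), tempfile())
  cat1 <- readCatalogue(fx$catalogue, source = "popA")
  cohort <- readCohort(fx$manifest, cat1, minCalls = 20)
  rep1 <- verifySexCounts(cohort, 3, 2)
  expect_true(rep1$pass)
  expect_equal(nrow(rep1$mismatches), 0L)

  expect_warning(rep2 <- verifySexCounts(cohort, 2, 3), "sex check failed")
  expect_false(rep2$pass)
  expect_error(verifySexCounts(cohort, 2, 3, strict = TRUE),
               "sex check failed")
  # declared counts must sum to the cohort size
  expect_error(verifySexCounts(cohort, 2, 2), "do not equal")
})
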