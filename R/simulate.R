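# Power simulation: cohort-vs-catalogue testing compared with a
# case-control association design, across cohort size, background allele
# frequency, number of causative SNPs, penetrance and non-genetic fraction.

#' Define a power-simulation scenario
#'
#' A scenario fixes the generative model for one simulated study: a cohort
#' of `nCohort` phenotype-positive individuals, of whom a fraction
#' `1 - nongeneticFraction` are genetic cases; each genetic case is caused
#' (with probability `penetrance`) by exactly one of `k` interchangeable
#' causative SNPs, chosen uniformly, and carries one rare allele of that SNP
#' (heterozygous, dominant model). Every chromosome not carrying a causal
#' allele draws the rare allele independently at the background population
#' frequency `q`. The cohort test applies the goodness-of-fit chi-squared
#' against `q` with Bonferroni correction over `mCorrection` SNPs at level
#' `alphaCohort`; the association comparator draws `nControls` control
#' individuals at frequency `q` and applies the 2x2 allele-count chi-squared
#' (no Yates) at raw threshold `assocThreshold`.
#'
#' @param nCohort Cohort size (individuals).
#' @param q Background rare-allele frequency, in (0, 0.5).
#' @param k Number of causative SNPs (>= 1).
#' @param penetrance Probability a genetic case is actually caused by its
#'   SNP (default 1).
#' @param nongeneticFraction Fraction of the cohort with no causal SNP
#'   (default 0).
#' @param mCorrection Multiple-testing denominator, the number of SNPs a
#'   full exome screen would test (default 121000).
#' @param alphaCohort Corrected significance level for the cohort test
#'   (default 0.01).
#' @param assocThreshold Raw p threshold for the association comparator
#'   (default 1e-8).
#' @param nControls Control-cohort size for the comparator (default
#'   `nCohort`).
#' @param replicates Monte-Carlo replicates (default 1000).
#' @param seed RNG seed for this scenario.
#' @return A list of class `PowerScenario`.
#' @export
powerScenario <- function(nCohort, q, k, penetrance = 1,
                          nongeneticFraction = 0, mCorrection = 121000,
                          alphaCohort = 0.01, assocThreshold = 1e-8,
                          nControls = nCohort, replicates = 1000, seed = 1) {
  stopifnot(nCohort >= 1, q > 0, q < 0.5, k >= 1,
            penetrance > 0, penetrance <= 1,
            nongeneticFraction >= 0, nongeneticFraction < 1,
            replicates >= 1)
  structure(list(nCohort = as.integer(nCohort), q = q, k = as.integer(k),
                 penetrance = penetrance,
                 nongeneticFraction = nongeneticFraction,
                 mCorrection = mCorrection, alphaCohort = alphaCohort,
                 assocThreshold = assocThreshold,
                 nControls = as.integer(nControls),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "PowerScenario")
}

#' Simulate one cohort replicate
#'
#' Draws the per-SNP rare-allele counts for one replicate of a scenario
#' under the generative model described in [powerScenario()]. Uses the
#' current RNG state (seed management is the caller's job; [runPowerGrid()]
#' seeds per scenario).
#'
#' @param scenario A `PowerScenario`.
#' @return A list: `rareCount` (length-`k` integer vector), `alleleTotal`
#'   (`2 * nCohort`, every locus autosomal diploid), `carriers` (causal
#'   carriers per SNP).
#' @export
simulateCohort <- function(scenario) {
  s <- scenario
  genetic <- round(s$nCohort * (1 - s$nongeneticFraction))
  causal <- stats::rbinom(1L, genetic, s$penetrance)
  carriers <- as.integer(stats::rmultinom(1L, causal, rep(1 / s$k, s$k)))
  chromTotal <- 2L * s$nCohort
  background <- stats::rbinom(s$k, chromTotal - carriers, s$q)
  list(rareCount = carriers + background, alleleTotal = chromTotal,
       carriers = carriers)
}

#' Cohort-test detection of simulated counts
#'
#' Tests each causative SNP's simulated rare-allele count against the
#' background frequency with the goodness-of-fit chi-squared (no Yates),
#' Bonferroni-corrected over `mCorrection` SNPs.
#'
#' @param counts Output of [simulateCohort()] (or a list with `rareCount`
#'   and `alleleTotal`).
#' @param scenario The `PowerScenario`.
#' @return Logical vector, per-SNP significance at `alphaCohort`.
#' @export
cohortDetect <- function(counts, scenario) {
  chi2 <- chi2Gof(counts$rareCount, counts$alleleTotal, scenario$q)
  pmin(1, scenario$mCorrection * chisqP(chi2)) < scenario$alphaCohort
}

#' Association-comparator detection of simulated counts
#'
#' Draws a control cohort of `nControls` individuals at the background
#' frequency and applies the 2x2 allele-count chi-squared (no Yates) per
#' SNP, significant at the raw `assocThreshold`. Uses the current RNG state.
#'
#' @inheritParams cohortDetect
#' @return Logical vector, per-SNP significance.
#' @export
assocDetect <- function(counts, scenario) {
  if (is.null(scenario$nControls) || scenario$nControls <= 0L)
    stop("association comparator requires nControls >= 1", call. = FALSE)
  ctrlTotal <- 2L * scenario$nControls
  ctrlRare <- stats::rbinom(length(counts$rareCount), ctrlTotal, scenario$q)
  chi2 <- chi2TwoByTwo(counts$rareCount, counts$alleleTotal - counts$rareCount,
                       ctrlRare, ctrlTotal - ctrlRare)
  chisqP(chi2) < scenario$assocThreshold
}

# Vectorised inner loop: all replicates of one scenario at once.
runScenario <- function(s) {
  set.seed(s$seed)
  R <- s$replicates; k <- s$k
  genetic <- round(s$nCohort * (1 - s$nongeneticFraction))
  chromTotal <- 2L * s$nCohort
  causal <- stats::rbinom(R, genetic, s$penetrance)
  carriers <- vapply(causal, function(sz)
    as.integer(stats::rmultinom(1L, sz, rep(1 / k, k))), integer(k))
  if (k == 1L) carriers <- matrix(carriers, nrow = 1L)
  background <- matrix(stats::rbinom(k * R, chromTotal - carriers, s$q), k, R)
  counts <- carriers + background

  chi2F <- chi2Gof(counts, chromTotal, s$q)
  sigF <- matrix(pmin(1, s$mCorrection * chisqP(chi2F)) < s$alphaCohort, k, R)

  ctrlTotal <- 2L * s$nControls
  ctrlRare <- matrix(stats::rbinom(k * R, ctrlTotal, s$q), k, R)
  chi2A <- chi2TwoByTwo(counts, chromTotal - counts,
                        ctrlRare, ctrlTotal - ctrlRare)
  sigA <- matrix(chisqP(chi2A) < s$assocThreshold, k, R)

  list(perSnpF = rowMeans(sigF), allF = mean(colSums(sigF) == k),
       anyF = mean(colSums(sigF) > 0),
       perSnpA = rowMeans(sigA), allA = mean(colSums(sigA) == k),
       anyA = mean(colSums(sigA) > 0))
}

#' Run a grid of power scenarios
#'
#' Estimates, for each scenario, the per-SNP detection power of the cohort
#' test and of the association comparator over Monte-Carlo replicates, and
#' summarises per parameter family (`nCohort`, `q`, `penetrance`,
#' `nongeneticFraction`) the largest number of causative SNPs `k` still
#' detected. Detection criteria:
#' \describe{
#'   \item{`all_gt_half`}{(default) every causative SNP has per-SNP power
#'     > 0.5;}
#'   \item{`any_gt_half`}{at least one causative SNP has per-SNP power
#'     > 0.5;}
#'   \item{`all_one_replicate`}{all `k` SNPs significant simultaneously in
#'     > 0.5 of replicates.}
#' }
#' Each scenario is seeded independently, so results are reproducible
#' bit-for-bit.
#'
#' @param scenarios A list of [powerScenario()] objects.
#' @param detection Detection criterion (see above).
#' @return A list of class `PowerGrid` with `results` (one row per scenario:
#'   parameters, per-SNP / all-SNP / any-SNP powers for both designs,
#'   `detected_cohort`, `detected_assoc`) and `summary` (per parameter
#'   family, `max_k_cohort` and `max_k_assoc`, 0 when no tested k is
#'   detected).
#' @export
runPowerGrid <- function(scenarios,
                         detection = c("all_gt_half", "any_gt_half",
                                       "all_one_replicate")) {
  detection <- match.arg(detection)
  if (inherits(scenarios, "PowerScenario")) scenarios <- list(scenarios)
  rows <- lapply(scenarios, function(s) {
    r <- runScenario(s)
    det <- function(perSnp, all_, any_) switch(detection,
      all_gt_half = all(perSnp > 0.5),
      any_gt_half = any(perSnp > 0.5),
      all_one_replicate = all_ > 0.5)
    data.frame(n_cohort = s$nCohort, q = s$q, k = s$k,
               penetrance = s$penetrance,
               nongenetic_fraction = s$nongeneticFraction,
               replicates = s$replicates, seed = s$seed,
               per_snp_power_cohort = mean(r$perSnpF),
               min_snp_power_cohort = min(r$perSnpF),
               power_all_cohort = r$allF, power_any_cohort = r$anyF,
               per_snp_power_assoc = mean(r$perSnpA),
               min_snp_power_assoc = min(r$perSnpA),
               power_all_assoc = r$allA, power_any_assoc = r$anyA,
               detected_cohort = det(r$perSnpF, r$allF, r$anyF),
               detected_assoc = det(r$perSnpA, r$allA, r$anyA))
  })
  results <- do.call(rbind, rows)
  fam <- interaction(results$n_cohort, results$q, results$penetrance,
                     results$nongenetic_fraction, drop = TRUE)
  summary <- do.call(rbind, lapply(split(results, fam), function(d) {
    data.frame(n_cohort = d$n_cohort[1L], q = d$q[1L],
               penetrance = d$penetrance[1L],
               nongenetic_fraction = d$nongenetic_fraction[1L],
               k_tested = paste(range(d$k), collapse = "-"),
               max_k_cohort = if (any(d$detected_cohort))
                 max(d$k[d$detected_cohort]) else 0L,
               max_k_assoc = if (any(d$detected_assoc))
                 max(d$k[d$detected_assoc]) else 0L)
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 detection = detection), class = "PowerGrid")
}

#' @export
print.PowerGrid <- function(x, ...) {
  cat("Power grid (", nrow(x$results), " scenarios, detection: ",
      x$detection, ")\n", sep = "")
  cat("Detected boundary (largest k detected) per parameter family:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Convenience constructor for a k-grid of scenarios
#'
#' Builds one scenario per `k` in `kRange` with shared parameters; seeds are
#' derived as `seed + k` so scenarios stay independently reproducible.
#'
#' @inheritParams powerScenario
#' @param kRange Integer vector of causative-SNP counts (default `1:10`).
#' @return A list of `PowerScenario` objects.
#' @export
scenarioGrid <- function(nCohort, q, kRange = 1:10, penetrance = 1,
                         nongeneticFraction = 0, mCorrection = 121000,
                         alphaCohort = 0.01, assocThreshold = 1e-8,
                         nControls = nCohort, replicates = 1000, seed = 1) {
  lapply(kRange, function(k)
    powerScenario(nCohort = nCohort, q = q, k = k, penetrance = penetrance,
                  nongeneticFraction = nongeneticFraction,
                  mCorrection = mCorrection, alphaCohort = alphaCohort,
                  assocThreshold = assocThreshold, nControls = nControls,
                  replicates = replicates, seed = seed + k))
}
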