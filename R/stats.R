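# Chi-squared testing of cohort vs catalogue frequencies, bound p-values,
# and multiple-testing correction.

# Goodness-of-fit chi-squared of (rare, common) allele counts against a
# fixed population frequency q. df = 1, no Yates continuity correction.
# Vectorised; the two-tailed deviation in either direction is captured by
# the df=1 upper tail. Core statistic of the whole method.
chi2Gof <- function(rare, total, q) {
  rare <- as.numeric(rare); total <- as.numeric(total)
  e1 <- q * total
  e2 <- (1 - q) * total
  (rare - e1)^2 / e1 + ((total - rare) - e2)^2 / e2
}

# Pearson chi-squared on the 2x2 allele-count table
# [rare1, common1; rare2, common2], no Yates correction. Vectorised; the
# catalogue's counts may be non-integer (frequency x allele number).
chi2TwoByTwo <- function(a, b, c, d) {
  # double arithmetic: margin products overflow 32-bit integers easily
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- n * (a * d - b * c)^2 / denom
  # a zero margin (e.g. no rare allele seen in either group) carries no
  # evidence of association: statistic 0, p = 1
  out[denom == 0] <- 0
  out
}

chisqP <- function(chi2) stats::pchisq(chi2, df = 1, lower.tail = FALSE)

#' Test cohort allele frequencies against a catalogue
#'
#' For each SNP, compares the cohort's rare-allele count with the catalogue
#' frequency using a two-tailed chi-squared test without Yates' continuity
#' correction (df = 1). Two modes:
#' \describe{
#'   \item{`goodness_of_fit`}{(default) the catalogue frequency `q` is taken
#'     as a fixed population parameter: observed counts
#'     `(r, t - r)` vs expected `(q t, (1 - q) t)`,
#'     `chi2 = sum((O - E)^2 / E)`.}
#'   \item{`two_sample`}{the catalogue is itself a finite sample:
#'     2x2 contingency of cohort vs catalogue allele counts (catalogue rare
#'     count `q * allele_number`); requires `allele_number`.}
#' }
#' SNPs that cannot be tested (no observed alleles, or `q` of exactly 0
#' or 1 in goodness-of-fit mode) are flagged `untestable` with `NA`
#' statistics. Sites where any expected cell falls below `expectedFloor`
#' are still tested but flagged `low_expected` — the chi-squared
#' approximation is doubtful there.
#'
#' @param freqs Cohort frequency table from [cohortFrequencies()] (or any
#'   data frame with the same columns).
#' @param catalogue An [SNPCatalogue-class]; SNPs are matched by
#'   (chromosome, position, rare allele).
#' @param mode `"goodness_of_fit"` or `"two_sample"`.
#' @param expectedFloor Expected-count floor below which a result is flagged
#'   (default 1.0).
#' @return A `data.frame` (one row per matched SNP): key columns, `source`,
#'   `rare_count`, `allele_total`, `freq`, `catalogue_freq`, `chi2`,
#'   `p_raw`, `direction` (`enriched` when the cohort frequency exceeds the
#'   catalogue's, else `depleted`), `low_expected`, `untestable`.
#' @export
chiSquareVsCatalogue <- function(freqs, catalogue,
                                 mode = c("goodness_of_fit", "two_sample"),
                                 expectedFloor = 1.0) {
  mode <- match.arg(mode)
  cd <- catalogueData(catalogue)
  ck <- catalogueKeys(catalogue)
  fk <- snpKey(freqs$chrom, freqs$pos, freqs$rare_allele)
  hit <- match(fk, ck)
  keep <- !is.na(hit)
  f <- freqs[keep, , drop = FALSE]
  q <- cd$rare_freq[hit[keep]]
  an <- cd$allele_number[hit[keep]]

  r <- f$rare_count; t <- f$allele_total
  untestable <- f$untestable | t == 0
  chi2 <- rep(NA_real_, nrow(f))
  low <- rep(FALSE, nrow(f))
  if (mode == "goodness_of_fit") {
    untestable <- untestable | q <= 0 | q >= 1
    ok <- !untestable
    chi2[ok] <- chi2Gof(r[ok], t[ok], q[ok])
    low[ok] <- pmin(q[ok] * t[ok], (1 - q[ok]) * t[ok]) < expectedFloor
  } else {
    if (any(is.na(an)))
      stop("two_sample mode requires allele_number for every catalogue SNP",
           call. = FALSE)
    ok <- !untestable
    a <- r[ok]; b <- t[ok] - r[ok]
    cc <- q[ok] * an[ok]; dd <- an[ok] - cc
    chi2[ok] <- chi2TwoByTwo(a, b, cc, dd)
    n <- a + b + cc + dd
    eMin <- pmin((a + b) * (a + cc), (a + b) * (b + dd),
                 (cc + dd) * (a + cc), (cc + dd) * (b + dd)) / n
    low[ok] <- eMin < expectedFloor
  }
  chi2[!untestable & chi2 < 0] <- 0   # guard against tiny negative rounding
  out <- data.frame(
    chrom = f$chrom, pos = f$pos, snp_id = f$snp_id,
    rare_allele = f$rare_allele,
    source = cd$source[hit[keep]],
    rare_count = r, allele_total = t,
    n_unknown_alleles = f$n_unknown_alleles,
    freq = f$freq, catalogue_freq = q,
    chi2 = chi2, p_raw = chisqP(chi2),
    direction = ifelse(!is.na(f$freq) & f$freq > q, "enriched", "depleted"),
    low_expected = low, untestable = untestable,
    mode = mode, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' P-value bounds under unknown alleles
#'
#' When some alleles at a SNP are unobserved (inadequate coverage, missing
#' genotypes), the cohort frequency is only known to lie between the bounds
#' obtained by assigning every unknown allele to the common or to the rare
#' allele. This function recomputes the goodness-of-fit test at those two
#' extreme allocations — each over `allele_total + n_unknown_alleles` total
#' alleles — and additionally reports the exact attainable p-value range
#' over *every* integer allocation of the unknowns. The chi-squared
#' statistic is convex in the allocated rare count, so its maximum over the
#' allocation interval sits at an endpoint while its minimum may sit at an
#' interior allocation (where the cohort frequency crosses the catalogue
#' frequency and the p-value rises to 1); `p_range_min`/`p_range_max` come
#' from evaluating the endpoints plus that interior optimum.
#'
#' @param freqs Cohort frequency table from [cohortFrequencies()].
#' @param catalogue An [SNPCatalogue-class].
#' @return A `data.frame` keyed like `freqs` with `p_raw_lower` (p at the
#'   all-common allocation, i.e. at `freq_lower`), `p_raw_upper` (p at the
#'   all-rare allocation, i.e. at `freq_upper`), and `p_range_min`,
#'   `p_range_max` bracketing every intermediate allocation. With no
#'   unknown alleles all four equal the test at the observed counts.
#' @export
boundPvalues <- function(freqs, catalogue) {
  cd <- catalogueData(catalogue)
  ck <- catalogueKeys(catalogue)
  fk <- snpKey(freqs$chrom, freqs$pos, freqs$rare_allele)
  hit <- match(fk, ck)
  keep <- !is.na(hit)
  f <- freqs[keep, , drop = FALSE]
  q <- cd$rare_freq[hit[keep]]

  n <- nrow(f)
  pl <- pu <- pmin_ <- pmax_ <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- f$rare_count[i]; t <- f$allele_total[i]; u <- f$n_unknown_alleles[i]
    if ((t + u) == 0 || q[i] <= 0 || q[i] >= 1) next
    total <- t + u
    pAt <- function(rr) chisqP(chi2Gof(rr, total, q[i]))
    pl[i] <- pAt(r)        # all unknowns common  -> frequency lower bound
    pu[i] <- pAt(r + u)    # all unknowns rare    -> frequency upper bound
    cand <- c(r, r + u)
    rStar <- q[i] * total  # chi2 minimum (chi2 = 0) sits here
    if (rStar > r && rStar < r + u)
      cand <- c(cand, max(r, floor(rStar)), min(r + u, ceiling(rStar)))
    pc <- vapply(cand, pAt, numeric(1))
    pmin_[i] <- min(pl[i], pu[i])
    pmax_[i] <- max(pc)
  }
  data.frame(chrom = f$chrom, pos = f$pos, rare_allele = f$rare_allele,
             p_raw_lower = pl, p_raw_upper = pu,
             p_range_min = pmin_, p_range_max = pmax_,
             stringsAsFactors = FALSE)
}

#' Multiple-testing correction and significance calling
#'
#' Applies Bonferroni (`p_bonferroni = min(1, m p_raw)`) and step-up
#' Benjamini-Hochberg (`q_fdr`) correction to the per-SNP raw p-values,
#' separately within each catalogue source, and flags SNPs significant when
#' the Bonferroni-corrected p falls below `alpha`. By default the
#' correction denominator `m` is the number of SNPs actually tested for
#' that source (untestable SNPs spend no correction budget); pass `m` to
#' correct over, e.g., the full catalogue size instead.
#'
#' @param results Test table from [chiSquareVsCatalogue()].
#' @param alpha Corrected significance level (default 0.01).
#' @param m Correction denominator; `NULL` (default) uses the per-source
#'   count of tested SNPs. May exceed the number of rows (e.g. the initial
#'   catalogue size).
#' @return The table with `m`, `p_bonferroni`, `q_fdr`, `significant`
#'   columns added, sorted by `p_raw` (untestable rows last).
#' @export
correctPvalues <- function(results, alpha = 0.01, m = NULL) {
  if (nrow(results) == 0L) {
    results$m <- integer(0); results$p_bonferroni <- numeric(0)
    results$q_fdr <- numeric(0); results$significant <- logical(0)
    return(results)
  }
  results$m <- NA_integer_
  results$p_bonferroni <- NA_real_
  results$q_fdr <- NA_real_
  results$significant <- NA
  for (src in unique(results$source)) {
    sel <- results$source == src & !results$untestable & !is.na(results$p_raw)
    mSrc <- if (is.null(m)) sum(sel) else m
    if (sum(sel) == 0L) next
    p <- results$p_raw[sel]
    results$m[sel] <- mSrc
    results$p_bonferroni[sel] <- pmin(1, mSrc * p)
    results$q_fdr[sel] <- stats::p.adjust(p, method = "BH", n = max(mSrc, length(p)))
    results$significant[sel] <- results$p_bonferroni[sel] < alpha
  }
  results <- results[order(results$untestable, results$p_raw), , drop = FALSE]
  rownames(results) <- NULL
  results
}
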