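# Sex-aware allele counting and cohort frequency computation.

#' Ploidy of a sample at a locus
#'
#' The number of allele copies a sample of a given sex is presumed to carry:
#' two on autosomes; on the X chromosome, two for females and one for males
#' outside the pseudoautosomal regions (two inside a PAR for either sex); on
#' the Y chromosome, one for males and zero for females. An unknown sex at a
#' sex-chromosome locus yields `NA` — the sample's alleles there cannot be
#' counted and are treated as unknown.
#'
#' @param sex `"male"`, `"female"`, or anything else for unknown
#'   (vectorised; recycled against the loci).
#' @param chrom,pos Locus coordinates (1-based).
#' @param par PAR intervals (see [defaultPAR()]).
#' @return Integer vector of ploidies (0, 1 or 2), `NA` where sex is
#'   required but unknown.
#' @export
#' @examples
#' ploidy("male", c("7", "X", "Y"), c(100, 5e6, 5e6))
ploidy <- function(sex, chrom, pos, par = defaultPAR()) {
  n <- max(length(sex), length(chrom), length(pos))
  sex <- rep_len(normSex(sex), n)
  chrom <- rep_len(normChrom(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  out <- rep(2L, n)
  isX <- chrom == "X"
  isY <- chrom == "Y"
  if (any(isX)) {
    par_ <- inPAR(chrom, pos, par)
    out[isX & !par_ & sex == "male"] <- 1L
    out[isX & !par_ & !(sex %in% c("male", "female"))] <- NA_integer_
  }
  out[isY & sex == "male"] <- 1L
  out[isY & sex == "female"] <- 0L
  out[isY & !(sex %in% c("male", "female"))] <- NA_integer_
  out
}

#' Cohort rare-allele frequencies with bounds under missing data
#'
#' Tallies rare-allele copies at each catalogue SNP across the cohort and
#' divides by the total number of presumed alleles — two per individual on
#' autosomes, one (male) or two (female) on sex chromosomes. Calls with
#' status `unknown` contribute no observed alleles; instead their ploidy is
#' accumulated as `n_unknown_alleles`, from which frequency bounds are
#' formed: `freq_lower` assumes every unobserved allele is the common one,
#' `freq_upper` assumes every one is rare,
#' \deqn{f_{lower} = r/(t+u), \quad f = r/t, \quad f_{upper} = (r+u)/(t+u),}
#' with `r` the rare count, `t` the observed allele total and `u` the
#' unknown alleles. SNPs with no observed alleles are kept but flagged
#' `untestable` (and excluded from testing and the multiple-testing
#' denominator downstream).
#'
#' Samples whose sex cannot be resolved have their X/Y alleles counted as
#' unknown (at the maximum possible ploidy), with a warning.
#'
#' @param object A [CohortCalls-class]; sexes are taken from [sampleSex()]
#'   (declared, falling back to inferred).
#' @param par PAR intervals (see [defaultPAR()]).
#' @return A `data.frame` with one row per catalogue SNP: the SNP key
#'   columns, `rare_count`, `allele_total`, `n_unknown_alleles`, `freq`,
#'   `freq_lower`, `freq_upper`, `untestable`.
#' @export
cohortFrequencies <- function(object, par = defaultPAR()) {
  cd <- snpData(object)
  sex <- sampleSex(object)
  rc <- rareCounts(object)
  st <- callStatus(object)
  nSnp <- nrow(cd); nSam <- ncol(object)

  # ploidy matrix: SNPs x samples
  P <- vapply(seq_len(nSam), function(j)
    ploidy(sex[j], cd$chrom, cd$pos, par), integer(nSnp))
  if (nSam == 1L) P <- matrix(P, ncol = 1L)

  sexUnknown <- is.na(P)
  if (any(sexUnknown)) {
    warning(sum(sexUnknown), " sex-chromosome call(s) from samples of ",
            "unresolved sex counted as unknown alleles")
    # maximum possible allele count: 2 on X, 1 on Y
    chromRep <- matrix(normChrom(cd$chrom), nSnp, nSam)
    P[sexUnknown] <- ifelse(chromRep[sexUnknown] == "Y", 1L, 2L)
  }
  unknown <- st == "unknown" | sexUnknown

  obs <- !unknown
  cnt <- pmin(ifelse(is.na(rc), 0L, rc), P)   # cap at ploidy (e.g. 1/1 on male X)
  rare_count <- rowSums(cnt * obs)
  allele_total <- rowSums(P * obs)
  n_unknown <- rowSums(P * unknown)
  if (any(rare_count > allele_total))
    stop("internal error: rare-allele count exceeds allele total",
         call. = FALSE)

  denomB <- allele_total + n_unknown
  out <- data.frame(
    chrom = cd$chrom, pos = cd$pos, snp_id = cd$snp_id,
    ref_allele = cd$ref_allele, rare_allele = cd$rare_allele,
    source = cd$source,
    rare_count = as.integer(rare_count),
    allele_total = as.integer(allele_total),
    n_unknown_alleles = as.integer(n_unknown),
    freq = ifelse(allele_total > 0, rare_count / allele_total, NA_real_),
    freq_lower = ifelse(denomB > 0, rare_count / denomB, NA_real_),
    freq_upper = ifelse(denomB > 0, (rare_count + n_unknown) / denomB,
                        NA_real_),
    untestable = allele_total == 0,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
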