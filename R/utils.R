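# Internal helpers shared across modules.

# Chromosome labels are keyed without a "chr" prefix and with X/Y upper-case,
# so "chr1"/"1" and "chrx"/"X" collapse to the same key.
normChrom <- function(chrom) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  toupper(x)
}

# The internal SNP key: chromosome, 1-based position, rare allele.
snpKey <- function(chrom, pos, rare_allele) {
  paste(normChrom(chrom), as.integer(pos), rare_allele, sep = ":")
}

siteKey <- function(chrom, pos) {
  paste(normChrom(chrom), as.integer(pos), sep = ":")
}

#' Pseudoautosomal regions of the X chromosome
#'
#' Default GRCh37 PAR1/PAR2 intervals on X. SNPs inside a PAR are diploid in
#' both sexes and are excluded from X-heterozygosity sex inference.
#'
#' @return A `GRanges` with the two X-chromosome pseudoautosomal intervals
#'   (1-based, chromosome named `"X"` without a `chr` prefix).
#' @export
#' @examples
#' defaultPAR()
defaultPAR <- function() {
  GenomicRanges::GRanges(
    seqnames = c("X", "X"),
    ranges = IRanges::IRanges(start = c(60001L, 154931044L),
                              end = c(2699520L, 155260560L))
  )
}

# TRUE for X-chromosome loci lying inside a PAR interval.
inPAR <- function(chrom, pos, par = defaultPAR()) {
  chrom <- normChrom(chrom)
  out <- rep(FALSE, length(chrom))
  isX <- chrom == "X"
  if (!any(isX) || length(par) == 0L) return(out)
  gr <- GenomicRanges::GRanges("X", IRanges::IRanges(pos[isX], pos[isX]))
  hits <- GenomicRanges::findOverlaps(gr, par)
  idx <- which(isX)
  out[idx[unique(S4Vectors::queryHits(hits))]] <- TRUE
  out
}

# vcfR::getFIX drops to a bare character vector for single-record files;
# always hand back a one-row-per-record data.frame.
getFixFrame <- function(vcf) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)
  as.data.frame(fix, stringsAsFactors = FALSE)
}

# Canonicalise sex labels to "male"/"female"/"unknown".
normSex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("m", "male")] <- "male"
  s[s %in% c("f", "female")] <- "female"
  s[!(s %in% c("male", "female"))] <- "unknown"
  s
}
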