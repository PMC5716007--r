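# Builders for small in-memory objects used across the tests.

# A catalogue straight from a data frame (bypassing file I/O).
makeCatalogue <- function(chrom, pos, rare_freq,
                          ref = "A", alt = "G", allele_number = NA_real_,
                          source = "test") {
  n <- length(pos)
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                   id = sprintf("rs%d", seq_len(n)),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   rare_freq = rare_freq,
                   allele_number = rep_len(allele_number, n))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  readCatalogue(tsv, source = source)
}

# A CohortCalls from explicit matrices; rows follow `catalogue`.
makeCohortCalls <- function(catalogue, rareCount, status = NULL, het = NULL,
                            sex = "female", inVcf = NULL) {
  CohortCalls(catalogue, rareCount, status = status, het = het,
              inVcf = inVcf, sex = sex)
}

# Write a minimal single-sample VCF; records is a data frame with columns
# chrom, pos, id, ref, alt, gt.
writeSampleVcf <- function(records, path = tempfile(fileext = ".vcf"),
                           sample = "s1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    if (nrow(records))
      sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
              records$chrom, records$pos, records$id, records$ref,
              records$alt, records$gt)), path)
  path
}

writeDepthTsv <- function(chrom, pos, depth,
                          path = tempfile(fileext = ".tsv")) {
  writeLines(sprintf("%s\t%d\t%d", chrom, as.integer(pos),
                     as.integer(depth)), path)
  path
}

# Independent oracle for the goodness-of-fit statistic: literal sum over
# the two cells, scalar arithmetic only.
oracleChi2 <- function(rare, total, q) {
  obs <- c(rare, total - rare)
  exp_ <- c(q * total, (1 - q) * total)
  s <- 0
  for (i in 1:2) s <- s + (obs[i] - exp_[i])^2 / exp_[i]
  s
}
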