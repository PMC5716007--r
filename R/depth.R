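# Per-base depth checking and the exon/gene coverage census.

#' Read a per-base depth table
#'
#' Depth input is the three-column dialect emitted by standard per-base depth
#' tools: chromosome, 1-based position, read depth, tab-separated, no header
#' required (a header line is detected and skipped).
#'
#' @param path Path to the depth TSV.
#' @return A keyed `data.table` (class `DepthTable`) for position lookup.
#' @export
readDepthTable <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, header = "auto", data.table = TRUE,
                      col.names = c("chrom", "pos", "depth"),
                      colClasses = list(character = 1)),
    error = function(e) stop("cannot read depth table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(dt) != 3L)
    stop("depth table '", path, "' must have 3 columns (chrom, pos, depth)",
         call. = FALSE)
  dt[, `:=`(key = siteKey(chrom, pos))]
  data.table::setkey(dt, key)
  class(dt) <- c("DepthTable", class(dt))
  dt
}

#' Look up read depth at a genomic position
#'
#' @param depth A `DepthTable` from [readDepthTable()].
#' @param chrom,pos Chromosome and 1-based position (vectorised).
#' @return Numeric depth per query; `NA` when the position is absent from
#'   the table (downstream filters treat absent as depth 0).
#' @export
siteDepth <- function(depth, chrom, pos) {
  stopifnot(inherits(depth, "DepthTable"))
  k <- siteKey(chrom, pos)
  depth$depth[match(k, depth$key)]
}

#' Demote calls at poorly covered sites
#'
#' Applies the read-depth cutoff to a cohort: a call (whether genotyped or
#' assumed homozygous common) at a site sequenced to fewer than `cutoff`
#' reads is unreliable for heterozygote detection and is demoted to
#' `unknown`, removing it from allele counting. Conversely, a catalogue SNP
#' absent from a sample's VCF whose site *is* covered at `cutoff` or more is
#' confirmed `ref_assumed`. Positions missing from a depth table count as
#' depth 0. Samples without a depth source are left untouched. The filter is
#' idempotent.
#'
#' @param object A [CohortCalls-class] whose `colData()$depth_path` names a
#'   per-sample depth table (see [readDepthTable()]).
#' @param cutoff Minimum read depth (default 20, below which heterozygosity
#'   cannot be called reliably).
#' @return The updated [CohortCalls-class]; the number of demoted calls is
#'   recorded in `metadata()$nDemoted` and reported in a message.
#' @export
applyDepthFilter <- function(object, cutoff = 20) {
  cd <- snpData(object)
  colDat <- SummarizedExperiment::colData(object)
  rc <- rareCounts(object)
  st <- callStatus(object)
  inv <- SummarizedExperiment::assay(object, "inVcf")
  ht <- SummarizedExperiment::assay(object, "het")
  nDemoted <- 0L
  for (j in seq_len(ncol(object))) {
    dp <- colDat$depth_path[j]
    if (is.na(dp)) next
    depth <- readDepthTable(dp)
    d <- siteDepth(depth, cd$chrom, cd$pos)
    d[is.na(d)] <- 0
    low <- d < cutoff
    demote <- low & st[, j] != "unknown"
    nDemoted <- nDemoted + sum(demote)
    st[demote, j] <- "unknown"
    rc[demote, j] <- NA_integer_
    ht[demote, j] <- NA
    # absent-from-VCF sites with adequate coverage are confirmed hom-common
    promote <- !low & !inv[, j] & st[, j] == "unknown"
    st[promote, j] <- "ref_assumed"
    rc[promote, j] <- 0L
  }
  SummarizedExperiment::assays(object)$rareCount <- rc
  SummarizedExperiment::assays(object)$status <- st
  SummarizedExperiment::assays(object)$het <- ht
  if (nDemoted > 0L)
    message(nDemoted, " call(s) demoted to unknown at sites below ", cutoff,
            "x coverage")
  S4Vectors::metadata(object)$nDemoted <-
    sum(S4Vectors::metadata(object)$nDemoted, nDemoted)
  object
}

# Read the 5-column exon definition table (BED coordinate convention:
# 0-based half-open) with gene symbol and exon id in columns 4-5.
readExonBed <- function(path) {
  bed <- data.table::fread(path, header = FALSE, data.table = FALSE,
                           colClasses = list(character = c(1, 4, 5)))
  if (ncol(bed) < 5L)
    stop("exon BED '", path, "' must have 5 columns ",
         "(chrom, start, end, gene, exon_id)", call. = FALSE)
  names(bed)[1:5] <- c("chrom", "start", "end", "gene", "exon_id")
  bed
}

#' Per-exon and per-gene coverage census
#'
#' Summarises sequencing depth over exon intervals across one or more
#' samples, the census used to decide which genes an exome can reliably
#' assay. Per exon: mean depth over all bases and samples, and the fraction
#' of (base, sample) observations at or above `cutoff`. Per gene: mean depth
#' over the union of its exonic bases (overlapping exons deduplicated), with
#' `adequately_covered` set when that mean strictly exceeds `cutoff - 1`
#' reads (i.e. > 19 at the default 20x cutoff).
#'
#' @param depthPaths Character vector of per-sample depth tables (named by
#'   sample; see [readDepthTable()]). Positions absent from a table count as
#'   depth 0.
#' @param bedPath Path to a 5-column exon table: chrom, start, end (0-based
#'   half-open), gene, exon_id.
#' @param cutoff Read-depth cutoff (default 20).
#' @return A list with `exons` and `genes` data frames and a `summary` list
#'   (`n_genes`, `n_adequate`, `fraction_adequate`).
#' @export
exonCoverageCensus <- function(depthPaths, bedPath, cutoff = 20) {
  stopifnot(length(depthPaths) >= 1L)
  bed <- readExonBed(bedPath)
  depths <- lapply(depthPaths, readDepthTable)

  baseDepth <- function(chrom, positions) {
    # matrix bases x samples, absent positions = 0
    vapply(depths, function(dt) {
      d <- siteDepth(dt, rep(chrom, length(positions)), positions)
      d[is.na(d)] <- 0
      as.numeric(d)
    }, numeric(length(positions)))
  }

  exonRows <- lapply(seq_len(nrow(bed)), function(i) {
    positions <- (bed$start[i] + 1L):bed$end[i]   # 1-based bases
    d <- baseDepth(bed$chrom[i], positions)
    data.frame(gene = bed$gene[i], exon_id = bed$exon_id[i],
               chrom = bed$chrom[i], start = bed$start[i], end = bed$end[i],
               n_bases = length(positions),
               mean_depth = mean(d),
               fraction_ge_cutoff = mean(d >= cutoff),
               cutoff = cutoff)
  })
  exons <- do.call(rbind, exonRows)

  geneRows <- lapply(split(seq_len(nrow(bed)), bed$gene), function(idx) {
    chrom <- bed$chrom[idx[1L]]
    ir <- IRanges::reduce(IRanges::IRanges(start = bed$start[idx] + 1L,
                                           end = bed$end[idx]))
    positions <- unlist(lapply(seq_along(ir), function(k)
      IRanges::start(ir)[k]:IRanges::end(ir)[k]))
    d <- baseDepth(chrom, positions)
    data.frame(gene = bed$gene[idx[1L]], n_bases = length(positions),
               mean_depth = mean(d),
               adequately_covered = mean(d) > cutoff - 1)
  })
  genes <- do.call(rbind, geneRows)
  rownames(genes) <- NULL
  list(exons = exons, genes = genes,
       summary = list(n_genes = nrow(genes),
                      n_adequate = sum(genes$adequately_covered),
                      fraction_adequate = mean(genes$adequately_covered)))
}
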