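# Protein-altering consequence filtering of significant SNPs.

consequenceVocabulary <- c("nonsense", "start_lost", "stop_lost",
                           "canonical_splice", "missense", "synonymous",
                           "other")

# Consequences that unequivocally alter the protein regardless of any
# prediction; missense additionally requires an external damaging flag.
alwaysAltering <- c("nonsense", "start_lost", "stop_lost", "canonical_splice")

#' Read SNP consequence annotations
#'
#' Annotation input is a tab-separated table with header and columns
#' `chrom`, `pos`, `rare_allele`, `consequence`, `damaging_flag`, `gene`.
#' `consequence` must come from the closed vocabulary `nonsense`,
#' `start_lost`, `stop_lost`, `canonical_splice` (the +/-2 intronic
#' dinucleotides), `missense`, `synonymous`, `other`. `damaging_flag` is an
#' externally supplied missense pathogenicity call (TRUE/FALSE or 1/0); it
#' is only meaningful for missense SNPs.
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame` of annotations.
#' @export
readAnnotations <- function(path) {
  ann <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = list(character = 1))
  need <- c("chrom", "pos", "rare_allele", "consequence", "damaging_flag",
            "gene")
  if (!all(need %in% names(ann)))
    stop("annotation table '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(ann$consequence), consequenceVocabulary)
  if (length(bad))
    stop("unknown consequence value: '", bad[1L], "'", call. = FALSE)
  ann$damaging_flag <- as.logical(ann$damaging_flag)
  ann
}

#' Restrict results to protein-altering SNPs
#'
#' Keeps only SNPs whose rare allele would unequivocally alter the protein:
#' nonsense, start-loss, stop-loss and canonical splice-site changes, plus
#' missense changes carrying an external damaging prediction. Synonymous and
#' other SNPs, missense without the damaging flag, and SNPs with no
#' annotation are dropped (the latter with a message). `includeAll = TRUE`
#' bypasses the filter entirely for analyses that want every SNP.
#'
#' @param results A test-result table (any data frame with `chrom`, `pos`,
#'   `rare_allele` columns, e.g. from [correctPvalues()]).
#' @param annotations Annotation table from [readAnnotations()] (or an
#'   equivalent data frame).
#' @param includeAll Bypass the filter and return `results` unchanged.
#' @return The filtered table, with `consequence`, `damaging_flag` and
#'   `gene` columns attached (unless `includeAll`).
#' @export
filterProteinAltering <- function(results, annotations, includeAll = FALSE) {
  if (includeAll) return(results)
  bad <- setdiff(unique(annotations$consequence), consequenceVocabulary)
  if (length(bad))
    stop("unknown consequence value: '", bad[1L], "'", call. = FALSE)
  rk <- snpKey(results$chrom, results$pos, results$rare_allele)
  ak <- snpKey(annotations$chrom, annotations$pos, annotations$rare_allele)
  hit <- match(rk, ak)
  unannotated <- is.na(hit)
  if (any(unannotated))
    message("dropped ", sum(unannotated), " unannotated SNP(s)")
  results <- results[!unannotated, , drop = FALSE]
  hit <- hit[!unannotated]
  cons <- annotations$consequence[hit]
  damaging <- annotations$damaging_flag[hit]
  keep <- cons %in% alwaysAltering |
    (cons == "missense" & !is.na(damaging) & damaging)
  out <- results[keep, , drop = FALSE]
  out$consequence <- cons[keep]
  out$damaging_flag <- damaging[keep]
  out$gene <- annotations$gene[hit][keep]
  rownames(out) <- NULL
  out
}
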