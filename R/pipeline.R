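# End-to-end pipeline: read cohort -> sex check -> depth filter ->
# frequencies -> chi-squared tests and corrections -> consequence filter.

#' Run the full cohort allele-frequency analysis
#'
#' Executes the whole workflow against one or more catalogues: per-sample
#' VCFs are aggregated over each catalogue's SNPs, sample sexes are inferred
#' from X heterozygosity and checked against the declared male/female
#' counts, calls at sites below the depth cutoff are demoted (when depth
#' tables are available), sex-aware cohort frequencies with bounds are
#' computed, each SNP is tested against the catalogue frequency
#' (chi-squared, no Yates), p-values are Bonferroni- and BH-corrected, and
#' the result is optionally restricted to protein-altering SNPs. One result
#' set is produced per catalogue, independently.
#'
#' @param manifest Sample manifest (data frame or TSV path): `sample_id`,
#'   `vcf_path`, optional `depth_path`, `sex`.
#' @param catalogues Named list/vector: [SNPCatalogue-class] objects or
#'   paths readable by [readCatalogue()]; names become source labels.
#' @param declaredMales,declaredFemales Declared cohort composition; when
#'   given, [verifySexCounts()] runs (a failure is a warning, or an error
#'   with `strictSex = TRUE`).
#' @param alpha Corrected significance level (default 0.01).
#' @param mode Test mode, see [chiSquareVsCatalogue()].
#' @param depthCutoff Read-depth cutoff (default 20); depth filtering runs
#'   for samples whose manifest names a depth table, unless
#'   `useDepth = FALSE`.
#' @param absentPolicy Policy for catalogue SNPs absent from a VCF before
#'   depth evidence, see [readCohort()].
#' @param correctByCatalogue Correct over the full catalogue size rather
#'   than the number of SNPs actually tested.
#' @param annotations Optional annotation table or TSV path; when given,
#'   results are filtered to protein-altering SNPs (see
#'   [filterProteinAltering()]) unless `includeAll = TRUE`.
#' @param includeAll Bypass the consequence filter.
#' @param strictSex Escalate a failed sex check to an error.
#' @param useDepth Set `FALSE` to skip depth filtering even when depth
#'   tables are available.
#' @param sexMinCalls Minimum called non-PAR X genotypes required before a
#'   sample's sex is inferred (see [inferSex()]); small SNP panels need a
#'   lower value than the exome-scale default of 50.
#' @param outdir Optional directory; when given, per-catalogue
#'   `results_<source>.tsv` and `frequencies_<source>.tsv`, a
#'   `sex_check.txt` report and a `run_log.txt` with stage counts are
#'   written.
#' @return A list: `results` (named per source, the corrected and filtered
#'   test tables, sorted by raw p), `frequencies` (per source),
#'   `sexReport`, and `log` (stage counts).
#' @export
runPipeline <- function(manifest, catalogues,
                        declaredMales = NULL, declaredFemales = NULL,
                        alpha = 0.01, mode = "goodness_of_fit",
                        depthCutoff = 20,
                        absentPolicy = "ref_assumed",
                        correctByCatalogue = FALSE,
                        annotations = NULL, includeAll = FALSE,
                        strictSex = FALSE, useDepth = TRUE,
                        sexMinCalls = 50L, outdir = NULL) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- readSampleManifest(manifest)
  if (methods::is(catalogues, "SNPCatalogue")) catalogues <- list(catalogues)
  if (is.null(names(catalogues)) || any(names(catalogues) == ""))
    names(catalogues) <- paste0("catalogue", seq_along(catalogues))
  catalogues <- lapply(names(catalogues), function(nm) {
    x <- catalogues[[nm]]
    if (methods::is(x, "SNPCatalogue")) x else readCatalogue(x, source = nm)
  })
  names(catalogues) <- vapply(catalogues,
                              function(x) catalogueData(x)$source[1L],
                              character(1))
  if (!is.null(annotations) && is.character(annotations))
    annotations <- readAnnotations(annotations)

  log <- list(n_samples = nrow(manifest))
  results <- frequencies <- list()
  sexReport <- NULL
  for (nm in names(catalogues)) {
    cohort <- readCohort(manifest, catalogues[[nm]],
                         absentPolicy = absentPolicy,
                         minCalls = sexMinCalls)
    if (is.null(sexReport) && !is.null(declaredMales) &&
        !is.null(declaredFemales))
      sexReport <- verifySexCounts(cohort, declaredMales, declaredFemales,
                                   strict = strictSex)
    hasDepth <- any(!is.na(SummarizedExperiment::colData(cohort)$depth_path))
    if (useDepth && hasDepth)
      cohort <- applyDepthFilter(cohort, cutoff = depthCutoff)
    freqs <- cohortFrequencies(cohort)
    res <- chiSquareVsCatalogue(freqs, catalogues[[nm]], mode = mode)
    bounds <- boundPvalues(freqs[freqs$n_unknown_alleles > 0 &
                                   !freqs$untestable, , drop = FALSE],
                           catalogues[[nm]])
    if (nrow(bounds)) {
      bk <- snpKey(bounds$chrom, bounds$pos, bounds$rare_allele)
      rk <- snpKey(res$chrom, res$pos, res$rare_allele)
      hit <- match(rk, bk)
      res$p_raw_lower <- bounds$p_raw_lower[hit]
      res$p_raw_upper <- bounds$p_raw_upper[hit]
    }
    res <- correctPvalues(res, alpha = alpha,
                          m = if (correctByCatalogue)
                            length(catalogues[[nm]]) else NULL)
    log[[paste0(nm, "_n_snps")]] <- length(catalogues[[nm]])
    log[[paste0(nm, "_n_tested")]] <- sum(!res$untestable)
    log[[paste0(nm, "_n_demoted")]] <-
      S4Vectors::metadata(cohort)$nDemoted %||% 0L
    log[[paste0(nm, "_n_significant")]] <-
      sum(res$significant, na.rm = TRUE)
    if (!is.null(annotations)) {
      res <- filterProteinAltering(res, annotations, includeAll = includeAll)
      log[[paste0(nm, "_n_after_consequence_filter")]] <- nrow(res)
    }
    results[[nm]] <- res
    frequencies[[nm]] <- freqs
  }

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    for (nm in names(results)) {
      write.table(results[[nm]],
                  file.path(outdir, paste0("results_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(frequencies[[nm]],
                  file.path(outdir, paste0("frequencies_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(sexReport)) {
      con <- file(file.path(outdir, "sex_check.txt"), "w")
      sink(con); print(sexReport); sink(); close(con)
    }
    writeLines(paste(names(log), unlist(log), sep = "\t"),
               file.path(outdir, "run_log.txt"))
  }
  list(results = results, frequencies = frequencies, sexReport = sexReport,
       log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
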