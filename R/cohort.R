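#' @title Cohort genotype calls over a SNP catalogue
#'
#' @description A `CohortCalls` extends `SummarizedExperiment`: rows are the
#' catalogue SNPs, columns are samples, and four assays hold the per-sample
#' call at each catalogue SNP:
#' \describe{
#'   \item{`rareCount`}{integer copies of the rare allele carried (`NA` when
#'     the call status is `unknown`).}
#'   \item{`status`}{`"called"` (genotyped in the sample's VCF),
#'     `"ref_assumed"` (absent from the VCF but assumed homozygous common),
#'     or `"unknown"` (no usable evidence).}
#'   \item{`het`}{logical, genotype was a two-allele heterozygote (used for
#'     X-based sex inference; `NA` when not called).}
#'   \item{`inVcf`}{logical, a usable VCF record covered this SNP (drives
#'     depth-based promotion/demotion of absent sites).}
#' }
#' `rowData` carries the catalogue columns; `colData` carries `sample_id`,
#' `declared_sex`, `inferred_sex`, `vcf_path`, `depth_path`.
#'
#' @seealso [readCohort()], [inferSex()], [applyDepthFilter()],
#'   [cohortFrequencies()]
#' @export
setClass("CohortCalls", contains = "SummarizedExperiment")

callStatuses <- c("called", "ref_assumed", "unknown")

setValidity("CohortCalls", function(object) {
  a <- SummarizedExperiment::assays(object)
  need <- c("rareCount", "status", "het", "inVcf")
  if (!all(need %in% names(a)))
    return(paste("missing assays:", paste(setdiff(need, names(a)), collapse = ", ")))
  st <- a$status
  if (!all(st %in% callStatuses))
    return("status assay contains values outside called/ref_assumed/unknown")
  rc <- a$rareCount
  if (any(is.na(rc) & st != "unknown"))
    return("rareCount may be NA only where status is unknown")
  if (any(!is.na(rc) & (rc < 0L | rc > 2L)))
    return("rareCount must lie in 0..2")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "declared_sex", "inferred_sex") %in% names(cd)))
    return("colData must carry sample_id, declared_sex, inferred_sex")
  if (anyDuplicated(cd$sample_id))
    return("sample_id must be unique within a cohort")
  TRUE
})

#' @describeIn CohortCalls Catalogue entries as a `data.frame` (one row per
#'   SNP, same order as the rows of the object).
#' @param object A `CohortCalls`.
#' @export
setGeneric("snpData", function(object) standardGeneric("snpData"))

#' @rdname CohortCalls-class
#' @export
setMethod("snpData", "CohortCalls", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

#' Accessors for CohortCalls
#'
#' @param object A [CohortCalls-class].
#' @return `rareCounts()`: integer matrix of rare-allele copies;
#'   `callStatus()`: character matrix of call statuses; `sampleSex()`: the
#'   per-sample sex used for allele counting (declared when known, otherwise
#'   inferred, otherwise `NA`); `inferredSex()`: the inferred sexes (`NA`
#'   before [inferSex()] has run).
#' @export
rareCounts <- function(object) SummarizedExperiment::assay(object, "rareCount")

#' @rdname rareCounts
#' @export
callStatus <- function(object) SummarizedExperiment::assay(object, "status")

#' @rdname rareCounts
#' @export
inferredSex <- function(object) {
  s <- SummarizedExperiment::colData(object)$inferred_sex
  stats::setNames(s, SummarizedExperiment::colData(object)$sample_id)
}

#' @rdname rareCounts
#' @export
sampleSex <- function(object) {
  cd <- SummarizedExperiment::colData(object)
  declared <- normSex(cd$declared_sex)
  inferred <- as.character(cd$inferred_sex)
  out <- ifelse(declared %in% c("male", "female"), declared,
                ifelse(inferred %in% c("male", "female"), inferred, NA))
  stats::setNames(out, cd$sample_id)
}

setMethod("show", "CohortCalls", function(object) {
  cat("CohortCalls:", nrow(object), "catalogue SNPs x", ncol(object),
      "samples\n")
  st <- callStatus(object)
  tab <- table(factor(st, levels = callStatuses))
  cat("calls:", paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "\n")
  sx <- sampleSex(object)
  cat("sex (declared/inferred):",
      paste(names(table(sx, useNA = "ifany")),
            as.integer(table(sx, useNA = "ifany")), sep = "=", collapse = ", "),
      "\n")
})

#' Construct a CohortCalls object from call matrices
#'
#' Builds the cohort container directly from a catalogue and a SNP-by-sample
#' matrix of rare-allele copies — the programmatic route when genotypes come
#' from somewhere other than per-sample VCFs (simulations, unit fixtures).
#' Unless given, `status` is derived from the counts (`NA` count =
#' `unknown`, positive = `called`, zero = `ref_assumed`), `het` marks called
#' single-copy genotypes, and `inVcf` marks called entries.
#'
#' @param catalogue An [SNPCatalogue-class]; its entries define the rows.
#' @param rareCount SNP-by-sample matrix of rare-allele copies (0-2, `NA`
#'   for unknown).
#' @param status Optional status matrix (`called`/`ref_assumed`/`unknown`).
#' @param het Optional logical heterozygosity matrix.
#' @param inVcf Optional logical matrix of VCF-backed entries.
#' @param sex Declared sexes, recycled across samples.
#' @param sampleIds Sample identifiers (default `s01`, `s02`, ...).
#' @return A [CohortCalls-class] object.
#' @export
CohortCalls <- function(catalogue, rareCount, status = NULL, het = NULL,
                        inVcf = NULL, sex = "unknown", sampleIds = NULL) {
  stopifnot(methods::is(catalogue, "SNPCatalogue"))
  rareCount <- as.matrix(rareCount)
  n <- nrow(rareCount); m <- ncol(rareCount)
  stopifnot(n == length(catalogue))
  if (is.null(status))
    status <- ifelse(is.na(rareCount), "unknown",
                     ifelse(rareCount > 0L, "called", "ref_assumed"))
  status <- matrix(status, n, m)
  if (is.null(het))
    het <- matrix(ifelse(status == "called",
                         !is.na(rareCount) & rareCount == 1L, NA), n, m)
  if (is.null(inVcf)) inVcf <- status == "called"
  inVcf <- matrix(inVcf, n, m)
  if (is.null(sampleIds)) sampleIds <- sprintf("s%02d", seq_len(m))
  rareCount <- matrix(as.integer(rareCount), n, m)
  dimn <- list(catalogueKeys(catalogue), sampleIds)
  dimnames(rareCount) <- dimnames(status) <- dimnames(het) <-
    dimnames(inVcf) <- dimn
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rareCount = rareCount, status = status, het = het,
                  inVcf = inVcf),
    rowData = S4Vectors::DataFrame(catalogueData(catalogue),
                                   row.names = dimn[[1L]]),
    colData = S4Vectors::DataFrame(sample_id = sampleIds,
                                   declared_sex = rep_len(normSex(sex), m),
                                   inferred_sex = NA_character_,
                                   vcf_path = NA_character_,
                                   depth_path = NA_character_,
                                   row.names = sampleIds))
  obj <- methods::new("CohortCalls", se)
  methods::validObject(obj)
  obj
}

# ---------------------------------------------------------------------------
# Per-sample VCF parsing

# Parse one sample's VCF restricted to the catalogue SNPs. Returns vectors
# aligned with the catalogue rows plus a count of skipped records.
readSampleVcf <- function(vcfPath, catalogue, sampleId = vcfPath,
                          absentPolicy = c("ref_assumed", "unknown")) {
  absentPolicy <- match.arg(absentPolicy)
  cd <- catalogueData(catalogue)
  n <- nrow(cd)
  rareCount <- integer(n)
  status <- rep(if (absentPolicy == "ref_assumed") "ref_assumed" else "unknown", n)
  if (absentPolicy == "unknown") rareCount <- rep(NA_integer_, n)
  het <- rep(NA, n)
  inVcf <- rep(FALSE, n)

  vcf <- tryCatch(vcfR::read.vcfR(vcfPath, verbose = FALSE),
                  error = function(e)
                    stop("cannot read VCF for sample '", sampleId, "' (",
                         vcfPath, "): ", conditionMessage(e), call. = FALSE))
  nSkipped <- 0L
  if (nrow(vcf@fix) == 0L)
    return(list(rareCount = rareCount, status = status, het = het,
                inVcf = inVcf, nSkipped = nSkipped))
  fix <- getFixFrame(vcf)
  gtm <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                  error = function(e)
                    stop("VCF for sample '", sampleId,
                         "' has no GT genotype field", call. = FALSE))
  gt <- gtm[, 1L]

  recSite <- siteKey(fix$CHROM, fix$POS)
  catSite <- siteKey(cd$chrom, cd$pos)
  recAlts <- strsplit(fix$ALT, ",", fixed = TRUE)

  for (i in which(catSite %in% recSite)) {
    recs <- which(recSite == catSite[i])
    # prefer the record that actually carries the catalogue's rare allele
    hasRare <- vapply(recs, function(r) cd$rare_allele[i] %in% recAlts[[r]],
                      logical(1))
    r <- if (any(hasRare)) recs[which(hasRare)[1L]] else recs[1L]
    g <- gt[r]
    if (is.na(g) || g == ".") {  # missing genotype
      status[i] <- "unknown"; rareCount[i] <- NA_integer_; inVcf[i] <- TRUE
      next
    }
    tokens <- strsplit(g, "[/|]")[[1L]]
    if (any(tokens == ".")) {    # half-call or missing
      status[i] <- "unknown"; rareCount[i] <- NA_integer_; inVcf[i] <- TRUE
      next
    }
    idx <- suppressWarnings(as.integer(tokens))
    nAlleles <- length(recAlts[[r]]) + 1L   # REF + ALTs
    if (any(is.na(idx)) || any(idx < 0L) || any(idx >= nAlleles)) {
      # GT allele index not matching REF/ALT: skip the record
      nSkipped <- nSkipped + 1L
      next
    }
    rareIdx <- match(cd$rare_allele[i], recAlts[[r]])  # 1-based among ALTs
    rc <- if (is.na(rareIdx)) 0L else sum(idx == rareIdx)
    rareCount[i] <- rc
    status[i] <- "called"
    het[i] <- length(idx) == 2L && idx[1L] != idx[2L]
    inVcf[i] <- TRUE
  }
  list(rareCount = rareCount, status = status, het = het, inVcf = inVcf,
       nSkipped = nSkipped)
}

#' Read a cohort of per-individual VCFs into a CohortCalls object
#'
#' Parses one VCF per sample, restricted to the SNPs of a reference
#' catalogue, and assembles the SNP-by-sample call matrix. VCF records not in
#' the catalogue are ignored; genotypes with a missing allele (`./.`, `./1`)
#' become `unknown`; genotypes whose allele indices do not match the record's
#' REF/ALT are skipped with a warning count. Catalogue SNPs absent from a
#' sample's VCF are `ref_assumed` (homozygous common) by default — the usual
#' convention for variant-only VCFs — or `unknown` with
#' `absentPolicy = "unknown"`; [applyDepthFilter()] later resolves absent
#' sites against actual read depth. A genotype carrying a non-catalogue
#' alternate allele contributes its non-rare alleles normally.
#'
#' @param manifest A `data.frame` (or path to a tab-separated file) with
#'   columns `sample_id`, `vcf_path`, optional `depth_path`, and `sex`
#'   (`male`/`female`/`unknown`, or `M`/`F`/`U`).
#' @param catalogue An [SNPCatalogue-class] defining the SNPs to genotype.
#' @param absentPolicy Status for catalogue SNPs absent from a sample's VCF
#'   when no depth evidence has been consulted.
#' @param inferSexes Run [inferSex()] on the assembled cohort (default
#'   `TRUE`).
#' @param ... Passed to [inferSex()] (thresholds, minimum call count, PAR).
#' @return A [CohortCalls-class] object.
#' @export
readCohort <- function(manifest, catalogue,
                       absentPolicy = c("ref_assumed", "unknown"),
                       inferSexes = TRUE, ...) {
  absentPolicy <- match.arg(absentPolicy)
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- readSampleManifest(manifest)
  stopifnot(all(c("sample_id", "vcf_path", "sex") %in% names(manifest)))
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest", call. = FALSE)
  missingVcf <- !file.exists(manifest$vcf_path)
  if (any(missingVcf))
    stop("VCF file not found for sample '",
         manifest$sample_id[which(missingVcf)[1L]], "': ",
         manifest$vcf_path[which(missingVcf)[1L]], call. = FALSE)

  cd <- catalogueData(catalogue)
  n <- nrow(cd); m <- nrow(manifest)
  rareCount <- matrix(NA_integer_, n, m)
  status <- matrix("unknown", n, m)
  het <- matrix(NA, n, m)
  inVcf <- matrix(FALSE, n, m)
  totalSkipped <- 0L
  for (j in seq_len(m)) {
    res <- readSampleVcf(manifest$vcf_path[j], catalogue,
                         sampleId = manifest$sample_id[j],
                         absentPolicy = absentPolicy)
    rareCount[, j] <- res$rareCount
    status[, j] <- res$status
    het[, j] <- res$het
    inVcf[, j] <- res$inVcf
    totalSkipped <- totalSkipped + res$nSkipped
  }
  if (totalSkipped > 0L)
    warning(totalSkipped, " VCF record(s) skipped: GT allele index not ",
            "matching REF/ALT")
  dimn <- list(catalogueKeys(catalogue), manifest$sample_id)
  dimnames(rareCount) <- dimnames(status) <- dimnames(het) <-
    dimnames(inVcf) <- dimn

  colDat <- S4Vectors::DataFrame(
    sample_id = manifest$sample_id,
    declared_sex = normSex(manifest$sex),
    inferred_sex = NA_character_,
    vcf_path = manifest$vcf_path,
    depth_path = if ("depth_path" %in% names(manifest))
      ifelse(manifest$depth_path %in% c("", "NA"), NA_character_,
             manifest$depth_path) else NA_character_,
    row.names = manifest$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rareCount = rareCount, status = status, het = het,
                  inVcf = inVcf),
    rowData = S4Vectors::DataFrame(cd, row.names = dimn[[1L]]),
    colData = colDat)
  obj <- methods::new("CohortCalls", se)
  S4Vectors::metadata(obj)$nSkippedRecords <- totalSkipped
  if (inferSexes) obj <- inferSex(obj, ...)
  methods::validObject(obj)
  obj
}

#' Read a sample manifest
#'
#' A manifest is a tab-separated table with header and columns `sample_id`,
#' `vcf_path`, optional `depth_path`, and `sex` (`M`/`F`/`U` or
#' `male`/`female`/`unknown`). Relative `vcf_path`/`depth_path` entries are
#' resolved against the manifest's own directory, so a fixture directory is
#' relocatable as a unit.
#'
#' @param path Path to the manifest TSV.
#' @return A `data.frame` with resolved paths.
#' @export
readSampleManifest <- function(path) {
  man <- data.table::fread(path, data.table = FALSE,
                           colClasses = "character")
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    ifelse(is.na(p) | p %in% c("", "NA") | grepl("^/", p), p,
           file.path(base, p))
  man$vcf_path <- resolve(man$vcf_path)
  if ("depth_path" %in% names(man))
    man$depth_path <- resolve(man$depth_path)
  man
}

# ---------------------------------------------------------------------------
# Sex inference and verification

#' Infer sample sex from X-chromosome heterozygosity
#'
#' Males are hemizygous on the non-pseudoautosomal X, so genuine heterozygous
#' calls there should be (near) absent. For each sample the fraction `h` of
#' heterozygous genotypes among called non-PAR X catalogue SNPs is computed:
#' `h < maleMax` infers male, `h > femaleMin` infers female, anything in
#' between — or fewer than `minCalls` usable X calls — is `ambiguous`.
#'
#' @param object A [CohortCalls-class].
#' @param minCalls Minimum called non-PAR X genotypes required (default 50).
#' @param maleMax Heterozygosity below which a sample is called male
#'   (default 0.05).
#' @param femaleMin Heterozygosity above which a sample is called female
#'   (default 0.20).
#' @param par PAR intervals excluded from inference (see [defaultPAR()]).
#' @return The object with `colData()$inferred_sex` filled in.
#' @export
inferSex <- function(object, minCalls = 50L, maleMax = 0.05, femaleMin = 0.20,
                     par = defaultPAR()) {
  cd <- snpData(object)
  onX <- normChrom(cd$chrom) == "X" & !inPAR(cd$chrom, cd$pos, par)
  st <- callStatus(object)[onX, , drop = FALSE]
  ht <- SummarizedExperiment::assay(object, "het")[onX, , drop = FALSE]
  called <- st == "called" & !is.na(ht)
  nCalled <- colSums(called)
  nHet <- colSums(called & ht)
  h <- ifelse(nCalled > 0L, nHet / nCalled, NA_real_)
  inferred <- rep("ambiguous", ncol(object))
  ok <- nCalled >= minCalls
  inferred[ok & h < maleMax] <- "male"
  inferred[ok & h > femaleMin] <- "female"
  colDat <- SummarizedExperiment::colData(object)
  colDat$inferred_sex <- inferred
  colDat$x_het_fraction <- h
  colDat$x_calls <- nCalled
  SummarizedExperiment::colData(object) <- colDat
  object
}

#' Verify inferred sexes against declared cohort composition
#'
#' Compares the inferred male/female counts with the counts declared for the
#' cohort; correct sexing matters because X-chromosome allele totals depend
#' on it. A disagreement is a warning by default, or an error with
#' `strict = TRUE`. Declared counts that do not sum to the number of samples
#' are always an error.
#'
#' @param object A [CohortCalls-class] on which [inferSex()] has run.
#' @param declaredMales,declaredFemales Declared numbers of males and
#'   females; they must sum to `ncol(object)`.
#' @param strict Treat a failed check as an error.
#' @return A list of class `SexCheckReport`: inferred counts, `pass`, and a
#'   `mismatches` data frame of samples whose declared and inferred sex
#'   disagree.
#' @export
verifySexCounts <- function(object, declaredMales, declaredFemales,
                            strict = FALSE) {
  nS <- ncol(object)
  if (declaredMales + declaredFemales != nS)
    stop("declared male + female counts (", declaredMales, " + ",
         declaredFemales, ") do not equal the number of samples (", nS, ")",
         call. = FALSE)
  colDat <- SummarizedExperiment::colData(object)
  inferred <- colDat$inferred_sex
  counts <- c(male = sum(inferred == "male"),
              female = sum(inferred == "female"),
              ambiguous = sum(inferred == "ambiguous"))
  pass <- counts[["male"]] == declaredMales &&
    counts[["female"]] == declaredFemales
  declared <- normSex(colDat$declared_sex)
  mism <- which(declared %in% c("male", "female") &
                  inferred %in% c("male", "female") & declared != inferred)
  mismatches <- data.frame(sample_id = colDat$sample_id[mism],
                           declared = declared[mism],
                           inferred = inferred[mism])
  report <- structure(list(declared_males = declaredMales,
                           declared_females = declaredFemales,
                           inferred_counts = counts, pass = pass,
                           mismatches = mismatches),
                      class = "SexCheckReport")
  if (!pass) {
    msg <- paste0("sex check failed: declared ", declaredMales, "M/",
                  declaredFemales, "F but inferred ", counts[["male"]], "M/",
                  counts[["female"]], "F/", counts[["ambiguous"]], "?")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  report
}

#' @export
print.SexCheckReport <- function(x, ...) {
  cat("Sex check:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("declared:", x$declared_males, "male,", x$declared_females, "female\n")
  cat("inferred:", paste(names(x$inferred_counts), x$inferred_counts,
                         sep = "=", collapse = ", "), "\n")
  if (nrow(x$mismatches)) {
    cat("mismatched samples:\n")
    print(x$mismatches, row.names = FALSE)
  }
  invisible(x)
}
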