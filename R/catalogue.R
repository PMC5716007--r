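#' @title Reference SNP frequency catalogue
#'
#' @description An `SNPCatalogue` holds one reference population's SNP
#' rare-allele frequencies: for each SNP its chromosome, 1-based position,
#' identifier, reference allele, rare allele, rare-allele frequency (always
#' normalised to at most 0.5), the number of catalogued alleles when known,
#' and a source label. It is the expectation against which cohort allele
#' frequencies are tested.
#'
#' @slot data A `data.frame` with columns `chrom`, `pos`, `snp_id`,
#'   `ref_allele`, `rare_allele`, `rare_freq`, `allele_number`, `source`.
#'
#' @seealso [readCatalogue()], [compareCatalogues()]
#' @export
setClass("SNPCatalogue", representation(data = "data.frame"))

catalogueColumns <- c("chrom", "pos", "snp_id", "ref_allele", "rare_allele",
                      "rare_freq", "allele_number", "source")

setValidity("SNPCatalogue", function(object) {
  d <- object@data
  msgs <- character(0)
  if (!all(catalogueColumns %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(catalogueColumns, names(d)), collapse = ", ")))
  if (nrow(d)) {
    if (any(is.na(d$rare_freq)) || any(d$rare_freq < 0) || any(d$rare_freq > 1))
      msgs <- c(msgs, "rare_freq must lie in [0, 1]")
    else if (any(d$rare_freq > 0.5))
      msgs <- c(msgs, "rare_freq must be <= 0.5 after normalisation")
    if (any(is.na(d$pos)) || any(d$pos < 1))
      msgs <- c(msgs, "pos must be a positive 1-based coordinate")
    an <- d$allele_number
    if (any(!is.na(an) & an <= 0))
      msgs <- c(msgs, "allele_number must be > 0 when present")
    key <- paste(snpKey(d$chrom, d$pos, d$rare_allele), d$source)
    if (anyDuplicated(key))
      msgs <- c(msgs, "(chrom, pos, rare_allele) must be unique per source")
  }
  if (length(msgs)) msgs else TRUE
})

# Internal constructor applying the rare-allele normalisation: rows whose
# frequency exceeds 0.5 have ref and rare alleles swapped and the frequency
# flipped to 1 - f (the catalogue's first allele is almost always the
# commoner one, but not always).
newCatalogue <- function(d) {
  d$pos <- as.integer(d$pos)
  d$rare_freq <- as.numeric(d$rare_freq)
  flip <- !is.na(d$rare_freq) & d$rare_freq > 0.5
  if (any(flip)) {
    warning(sum(flip), " entr", if (sum(flip) == 1L) "y" else "ies",
            " with rare_freq > 0.5: alleles swapped and frequency flipped")
    tmp <- d$ref_allele[flip]
    d$ref_allele[flip] <- d$rare_allele[flip]
    d$rare_allele[flip] <- tmp
    d$rare_freq[flip] <- 1 - d$rare_freq[flip]
  }
  rownames(d) <- NULL
  methods::new("SNPCatalogue", data = d[, catalogueColumns])
}

#' @describeIn SNPCatalogue Number of catalogue entries.
#' @param x,object An `SNPCatalogue`.
#' @export
setMethod("length", "SNPCatalogue", function(x) nrow(x@data))

#' Access the entries of an SNPCatalogue
#'
#' @param x An [SNPCatalogue-class] object.
#' @return `catalogueData()` returns the underlying `data.frame` (one row per
#'   SNP entry); `catalogueKeys()` returns the `chrom:pos:rare_allele` key
#'   strings used to match SNPs across catalogues and cohorts.
#' @export
catalogueData <- function(x) {
  stopifnot(methods::is(x, "SNPCatalogue"))
  x@data
}

#' @rdname catalogueData
#' @export
catalogueKeys <- function(x) {
  d <- catalogueData(x)
  snpKey(d$chrom, d$pos, d$rare_allele)
}

setMethod("show", "SNPCatalogue", function(object) {
  d <- object@data
  cat("SNPCatalogue with", nrow(d), "entries",
      if (nrow(d)) paste0("(source: ", paste(unique(d$source), collapse = ", "), ")"),
      "\n")
  if (nrow(d)) print(utils::head(d, 5))
  if (nrow(d) > 5) cat("...\n")
})

#' Load a reference SNP frequency catalogue
#'
#' Reads a catalogue either from a tab-separated table (columns `chrom`,
#' `pos`, `id`, `ref`, `alt`, `rare_freq` and optionally `allele_number`,
#' with a header line) or from a sites-only VCF whose INFO field carries the
#' alternate-allele frequency. Multi-allelic VCF sites are expanded to one
#' entry per alternate allele, each with its own frequency. Entries with a
#' missing frequency are dropped (with a message); a frequency outside
#' \[0, 1\] or a malformed line is a hard error naming the line. Entries with
#' frequency above 0.5 are normalised by swapping alleles and flipping the
#' frequency, with a warning.
#'
#' @param path Path to the catalogue file.
#' @param source Label recorded in the `source` column (e.g. the population
#'   database the frequencies come from).
#' @param format `"auto"` (by file extension), `"tsv"` or `"vcf"`.
#' @param afField INFO key holding alternate-allele frequencies in a VCF
#'   catalogue (default `"AF"`; comma-separated for multi-allelic sites).
#' @param anField INFO key holding the catalogued allele number (default
#'   `"AN"`); missing values leave `allele_number` as `NA`.
#' @param evsLowestAllele If `TRUE`, replicate a known defect of one public
#'   catalogue export: at multi-allelic sites keep only the lowest-frequency
#'   alternate allele instead of expanding all of them. Off by default.
#' @return An [SNPCatalogue-class] object.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tid\tref\talt\trare_freq\tallele_number",
#'              "1\t12345\trs1\tA\tG\t0.08\t10000"), tsv)
#' cat1 <- readCatalogue(tsv, source = "demo")
#' catalogueData(cat1)
readCatalogue <- function(path, source,
                          format = c("auto", "tsv", "vcf"),
                          afField = "AF", anField = "AN",
                          evsLowestAllele = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    readCatalogueTsv(path, source)
  } else {
    readCatalogueVcf(path, source, afField, anField, evsLowestAllele)
  }
}

readCatalogueTsv <- function(path, source) {
  d <- tryCatch(
    data.table::fread(path, header = TRUE, sep = "\t", colClasses = "character",
                      data.table = FALSE),
    error = function(e) stop("malformed catalogue TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(d) < 6L)
    stop("catalogue TSV '", path, "' has ", ncol(d),
         " columns; expected at least 6", call. = FALSE)
  names(d)[1:6] <- c("chrom", "pos", "snp_id", "ref_allele", "rare_allele",
                     "rare_freq")
  d$allele_number <- if (ncol(d) >= 7L) d[[7L]] else NA_character_
  # +1 for the header: reported line numbers refer to the file.
  lineno <- seq_len(nrow(d)) + 1L
  pos <- suppressWarnings(as.integer(d$pos))
  freq <- suppressWarnings(as.numeric(d$rare_freq))
  an <- suppressWarnings(as.numeric(d$allele_number))
  freqMissing <- is.na(d$rare_freq) | d$rare_freq %in% c("", "NA", ".")
  bad <- which(is.na(pos) | (is.na(freq) & !freqMissing))
  if (length(bad))
    stop("malformed catalogue line ", lineno[bad[1]], " in '", path, "'",
         call. = FALSE)
  out <- data.frame(chrom = d$chrom, pos = pos, snp_id = d$snp_id,
                    ref_allele = d$ref_allele, rare_allele = d$rare_allele,
                    rare_freq = freq, allele_number = an,
                    source = source, stringsAsFactors = FALSE)
  finishCatalogue(out, path, lineno)
}

readCatalogueVcf <- function(path, source, afField, anField, evsLowestAllele) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- getFixFrame(vcf)
  af <- vcfR::extract.info(vcf, element = afField)
  an <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = anField)))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  afs <- strsplit(ifelse(is.na(af), "", af), ",", fixed = TRUE)
  nalt <- lengths(alts)
  mismatch <- which(lengths(afs) > 0L & lengths(afs) != nalt)
  if (length(mismatch))
    stop("VCF catalogue '", path, "': ", afField, " count does not match ALT",
         " count at ", fix$CHROM[mismatch[1]], ":", fix$POS[mismatch[1]],
         call. = FALSE)
  idx <- rep(seq_len(nrow(fix)), nalt)
  out <- data.frame(
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    snp_id = fix$ID[idx],
    ref_allele = fix$REF[idx],
    rare_allele = unlist(alts),
    rare_freq = suppressWarnings(as.numeric(unlist(
      lapply(seq_along(afs), function(i)
        if (length(afs[[i]])) afs[[i]] else rep(NA_character_, nalt[i]))))),
    allele_number = an[idx],
    source = source, stringsAsFactors = FALSE)
  if (evsLowestAllele) {
    # Compatibility switch: keep only the lowest-frequency alternate allele
    # at each site, replicating a flawed multi-allelic export.
    site <- siteKey(out$chrom, out$pos)
    keep <- unlist(lapply(split(seq_len(nrow(out)), site), function(i) {
      f <- out$rare_freq[i]
      if (all(is.na(f))) i[1L] else i[which.min(f)]
    }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
  }
  finishCatalogue(out, path, lineno = NULL)
}

finishCatalogue <- function(out, path, lineno = NULL) {
  dropped <- is.na(out$rare_freq)
  if (any(dropped)) {
    message("dropped ", sum(dropped), " catalogue entr",
            if (sum(dropped) == 1L) "y" else "ies", " with missing frequency")
    out <- out[!dropped, , drop = FALSE]
    if (!is.null(lineno)) lineno <- lineno[!dropped]
  }
  oob <- which(out$rare_freq < 0 | out$rare_freq > 1)
  if (length(oob)) {
    where <- if (!is.null(lineno)) paste0("line ", lineno[oob[1]]) else
      paste0(out$chrom[oob[1]], ":", out$pos[oob[1]])
    stop("frequency outside [0, 1] at ", where, " in '", path, "'",
         call. = FALSE)
  }
  obj <- newCatalogue(out)
  methods::validObject(obj)
  obj
}

#' Write a catalogue back to a TSV file
#'
#' Inverse of [readCatalogue()] for the TSV dialect; a written catalogue
#' reloads with every field intact.
#'
#' @param x An [SNPCatalogue-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCatalogue <- function(x, path) {
  d <- catalogueData(x)
  out <- data.frame(chrom = d$chrom, pos = d$pos, id = d$snp_id,
                    ref = d$ref_allele, alt = d$rare_allele,
                    rare_freq = d$rare_freq, allele_number = d$allele_number)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @title Comparison of two SNP catalogues
#' @description Result of [compareCatalogues()]: SNPs (matched by chromosome,
#'   position and rare allele) present in both catalogues, and how many of
#'   those differ in rare-allele frequency by more than a threshold.
#' @slot nShared Number of SNPs present in both catalogues.
#' @slot nDiscordant Number of shared SNPs with `|f_a - f_b|` strictly above
#'   the threshold.
#' @slot threshold The frequency-difference threshold used.
#' @slot discordantIds `snp_id`s of the discordant SNPs.
#' @export
setClass("CatalogueComparison",
         representation(nShared = "integer", nDiscordant = "integer",
                        threshold = "numeric", discordantIds = "character"))

setValidity("CatalogueComparison", function(object) {
  if (object@nDiscordant > object@nShared)
    return("nDiscordant cannot exceed nShared")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0, 1)")
  TRUE
})

setMethod("show", "CatalogueComparison", function(object) {
  cat("CatalogueComparison:", object@nShared, "shared SNPs,",
      object@nDiscordant, "discordant (|freq difference| >",
      object@threshold, ")\n")
  if (object@nShared > 0)
    cat(sprintf("discordant fraction: %.1f%%\n",
                100 * object@nDiscordant / object@nShared))
})

#' @rdname compareCatalogues
#' @export
nShared <- function(x) x@nShared
#' @rdname compareCatalogues
#' @export
nDiscordant <- function(x) x@nDiscordant
#' @rdname compareCatalogues
#' @export
discordantIds <- function(x) x@discordantIds

#' Compare rare-allele frequencies between two catalogues
#'
#' Matches SNPs between two catalogues by (chromosome, position, rare allele)
#' and counts those whose frequencies differ by strictly more than
#' `threshold`. A difference of exactly the threshold is concordant. Useful
#' for quantifying disagreement between two reference populations before
#' choosing one (or testing against both).
#'
#' @param a,b [SNPCatalogue-class] objects.
#' @param threshold Frequency difference above which a shared SNP counts as
#'   discordant (default 0.05, i.e. a 5 percentage-point difference).
#' @param x A `CatalogueComparison` (for the accessors).
#' @return A [CatalogueComparison-class]; accessors `nShared()`,
#'   `nDiscordant()`, `discordantIds()`.
#' @export
compareCatalogues <- function(a, b, threshold = 0.05) {
  stopifnot(methods::is(a, "SNPCatalogue"), methods::is(b, "SNPCatalogue"))
  da <- catalogueData(a); db <- catalogueData(b)
  ka <- catalogueKeys(a); kb <- catalogueKeys(b)
  shared <- intersect(ka, kb)
  fa <- da$rare_freq[match(shared, ka)]
  fb <- db$rare_freq[match(shared, kb)]
  disc <- abs(fa - fb) > threshold
  methods::new("CatalogueComparison",
               nShared = length(shared),
               nDiscordant = sum(disc),
               threshold = threshold,
               discordantIds = da$snp_id[match(shared, ka)][disc])
}
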