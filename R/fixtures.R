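# Synthetic data generator: catalogues, per-sample VCFs, depth tables,
# exon definitions and consequence annotations with known ground truth, so
# the whole pipeline is testable offline and byte-reproducibly.

#' Specify a synthetic cohort fixture
#'
#' Defines everything [makeFixture()] needs to emit a self-consistent
#' synthetic study: a catalogue of SNPs with population frequencies, one
#' variant-only VCF per sample with sex-consistent genotypes (males are
#' haploid, never heterozygous, on the non-PAR X), per-sample per-base depth
#' tables, an exon table, consequence annotations and a ground-truth table
#' of the realised cohort allele counts.
#'
#' Null SNPs draw cohort genotypes at exactly the catalogue frequency;
#' `spikes` adds SNPs whose cohort frequency differs from the catalogue
#' frequency (the signal the pipeline should detect). Missing data is
#' emulated jointly: a masked (sample, SNP) pair is withheld from the VCF
#' *and* its depth is set below the cutoff, so the pipeline must treat it as
#' unknown.
#'
#' @param nSamples Number of samples.
#' @param nMales Number of males among them (declared and generated).
#' @param nSnps Number of null catalogue SNPs.
#' @param propX Fraction of null SNPs placed on (non-PAR) X.
#' @param missingness Per-call probability of masking (default 0).
#' @param meanDepth Mean depth at adequately covered sites; generated depths
#'   are `depthFloor + Poisson(meanDepth - depthFloor)` so unmasked sites
#'   always pass the cutoff.
#' @param depthFloor Minimum depth at unmasked sites (default 20).
#' @param lowDepth Depth written at masked sites (default 5).
#' @param freqRange Range the null frequencies are drawn from (default
#'   0.05-0.45).
#' @param spikes `NULL`, or a data frame with columns `cohort_freq`,
#'   `catalogue_freq`, `consequence` (one spiked autosomal SNP per row).
#' @param emitHomRef Also write explicit `0/0` records for homozygous-common
#'   genotypes (default `FALSE`: variant-only VCFs).
#' @param alleleNumber Catalogue allele number (default 10000).
#' @param seed Seed fixing every generated byte.
#' @return A list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(nSamples = 20, nMales = 10, nSnps = 200,
                        propX = 0.1, missingness = 0, meanDepth = 60,
                        depthFloor = 20, lowDepth = 5,
                        freqRange = c(0.05, 0.45), spikes = NULL,
                        emitHomRef = FALSE, alleleNumber = 10000,
                        seed = 1) {
  stopifnot(nSamples >= 1, nMales >= 0, nMales <= nSamples, nSnps >= 1,
            propX >= 0, propX <= 1, missingness >= 0, missingness < 1,
            lowDepth < depthFloor)
  if (!is.null(spikes))
    stopifnot(all(c("cohort_freq", "catalogue_freq", "consequence")
                  %in% names(spikes)))
  structure(list(nSamples = as.integer(nSamples), nMales = as.integer(nMales),
                 nSnps = as.integer(nSnps), propX = propX,
                 missingness = missingness, meanDepth = meanDepth,
                 depthFloor = depthFloor, lowDepth = lowDepth,
                 freqRange = freqRange, spikes = spikes,
                 emitHomRef = emitHomRef, alleleNumber = alleleNumber,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Generate a synthetic cohort fixture on disk
#'
#' Writes, under `outdir`: `catalogue.tsv` and `catalogue.vcf` (the same
#' catalogue in both dialects), `sample<i>.vcf` and `sample<i>.depth.tsv`
#' per sample, `exons.bed`, `annotations.tsv`, `truth.tsv` (realised
#' rare-allele count, allele total and frequency per SNP),
#' `manifest.tsv` (the sample manifest [readCohort()] consumes) and
#' `MANIFEST.txt` (every file with its md5 checksum). All randomness is
#' fixed by `spec$seed`: the same spec written twice produces identical
#' checksums.
#'
#' @param spec A [fixtureSpec()].
#' @param outdir Output directory (created if needed; must be writable).
#' @return Invisibly, a list: `dir`, `files` (the checksum manifest),
#'   `manifest` (the sample manifest data frame), `truth`, `catalogue`
#'   (paths and data frames).
#' @export
makeFixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", outdir, "'", call. = FALSE)
  if (file.access(outdir, mode = 2L) != 0L)
    stop("output directory '", outdir, "' is not writable", call. = FALSE)
  set.seed(spec$seed)

  # --- catalogue ----------------------------------------------------------
  nX <- round(spec$nSnps * spec$propX)
  nAuto <- spec$nSnps - nX
  chromAuto <- sample(as.character(1:5), nAuto, replace = TRUE)
  chrom <- c(chromAuto, rep("X", nX))
  # non-PAR X: PAR1 ends at 2,699,520; PAR2 starts at 154,931,044
  pos <- integer(spec$nSnps)
  pos[seq_len(nAuto)] <- sample.int(5e7 - 1e5, nAuto) + 1e5
  if (nX > 0) pos[nAuto + seq_len(nX)] <- sample.int(1.5e8 - 3e6, nX) + 3e6
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, spec$nSnps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  trueFreq <- round(runif(spec$nSnps, spec$freqRange[1], spec$freqRange[2]), 4)
  catFreq <- trueFreq                       # null SNPs: cohort == catalogue
  cons <- sample(consequenceVocabulary, spec$nSnps, replace = TRUE,
                 prob = c(.05, .02, .02, .05, .36, .30, .20))

  if (!is.null(spec$spikes)) {
    nSp <- nrow(spec$spikes)
    chrom <- c(chrom, rep("2", nSp))
    pos <- c(pos, 9e7 + seq_len(nSp) * 1000L)
    refSp <- sample(bases, nSp, replace = TRUE)
    ref <- c(ref, refSp)
    alt <- c(alt, vapply(refSp, function(r) sample(setdiff(bases, r), 1L),
                         character(1)))
    trueFreq <- c(trueFreq, spec$spikes$cohort_freq)
    catFreq <- c(catFreq, spec$spikes$catalogue_freq)
    cons <- c(cons, spec$spikes$consequence)
  }
  nTot <- length(chrom)
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
  trueFreq <- trueFreq[ord]; catFreq <- catFreq[ord]; cons <- cons[ord]
  spiked <- ord > spec$nSnps
  snpId <- sprintf("rs%06d", seq_len(nTot) * 7L + 100000L)
  damaging <- ifelse(cons == "missense", runif(nTot) < 0.5, FALSE)
  # spiked SNPs should survive the protein-altering filter
  damaging[spiked & cons == "missense"] <- TRUE

  catTsv <- file.path(outdir, "catalogue.tsv")
  catDf <- data.frame(chrom = chrom, pos = pos, id = snpId, ref = ref,
                      alt = alt,
                      rare_freq = format(catFreq, scientific = FALSE,
                                         trim = TRUE),
                      allele_number = spec$alleleNumber)
  write.table(catDf, catTsv, sep = "\t", quote = FALSE, row.names = FALSE)
  catVcf <- file.path(outdir, "catalogue.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele Number\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tAF=%s;AN=%d",
                       chrom, pos, snpId, ref, alt,
                       format(catFreq, scientific = FALSE, trim = TRUE),
                       as.integer(spec$alleleNumber))),
             catVcf)

  # --- genotypes ----------------------------------------------------------
  sex <- c(rep("male", spec$nMales), rep("female", spec$nSamples - spec$nMales))
  sampleId <- sprintf("sample%02d", seq_len(spec$nSamples))
  onX <- normChrom(chrom) == "X"
  G <- matrix(0L, nTot, spec$nSamples)     # realised rare-allele copies
  P <- matrix(2L, nTot, spec$nSamples)     # ploidy
  for (j in seq_len(spec$nSamples)) {
    pl <- ifelse(onX & sex[j] == "male", 1L, 2L)
    P[, j] <- pl
    G[, j] <- stats::rbinom(nTot, pl, trueFreq)
  }
  masked <- matrix(runif(nTot * spec$nSamples) < spec$missingness,
                   nTot, spec$nSamples)

  # --- per-sample VCFs and depth tables ----------------------------------
  vcfPaths <- depthPaths <- character(spec$nSamples)
  for (j in seq_len(spec$nSamples)) {
    vcfPaths[j] <- file.path(outdir, paste0(sampleId[j], ".vcf"))
    keep <- !masked[, j] & (G[, j] > 0L | spec$emitHomRef)
    gt <- character(nTot)
    dip <- P[, j] == 2L
    gt[dip] <- c("0/0", "0/1", "1/1")[G[, j][dip] + 1L]
    gt[!dip] <- c("0", "1")[G[, j][!dip] + 1L]
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                        "\tFORMAT\t", sampleId[j]),
                 sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                         chrom[keep], pos[keep], snpId[keep], ref[keep],
                         alt[keep], gt[keep])),
               vcfPaths[j])
    depthPaths[j] <- file.path(outdir, paste0(sampleId[j], ".depth.tsv"))
    depth <- spec$depthFloor +
      stats::rpois(nTot, max(spec$meanDepth - spec$depthFloor, 0))
    depth[masked[, j]] <- spec$lowDepth
    # per-base rows over each SNP's 21-base exon window, constant per SNP
    off <- -10:10
    writeLines(sprintf("%s\t%d\t%d",
                       rep(chrom, each = 21L),
                       as.integer(outer(off, pos, `+`)),
                       rep(depth, each = 21L)),
               depthPaths[j])
  }

  # --- exons, annotations, truth, manifests ------------------------------
  # one compact 21-base exon per SNP; five consecutive exons form a gene
  bedPath <- file.path(outdir, "exons.bed")
  gene <- character(nTot)
  bedRows <- character(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)           # already position-sorted within chrom
    block <- ceiling(seq_along(idx) / 5)
    for (b in unique(block)) {
      ii <- idx[block == b]
      g <- sprintf("GENE%s_%02d", ch, b)
      gene[ii] <- g
      bedRows <- c(bedRows,
                   sprintf("%s\t%d\t%d\t%s\t%s_ex%d", ch, pos[ii] - 11L,
                           pos[ii] + 10L, g, g, seq_along(ii)))
    }
  }
  writeLines(bedRows, bedPath)

  annPath <- file.path(outdir, "annotations.tsv")
  write.table(data.frame(chrom = chrom, pos = pos, rare_allele = alt,
                         consequence = cons,
                         damaging_flag = tolower(as.character(damaging)),
                         gene = gene),
              annPath, sep = "\t", quote = FALSE, row.names = FALSE)

  truthPath <- file.path(outdir, "truth.tsv")
  truth <- data.frame(chrom = chrom, pos = pos, snp_id = snpId,
                      rare_allele = alt, spiked = spiked,
                      true_count = rowSums(pmin(G, P)),
                      true_total = rowSums(P))
  truth$true_freq <- truth$true_count / truth$true_total
  write.table(truth, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)

  manifestPath <- file.path(outdir, "manifest.tsv")
  manifest <- data.frame(sample_id = sampleId, vcf_path = vcfPaths,
                         depth_path = depthPaths,
                         sex = ifelse(sex == "male", "M", "F"))
  # the on-disk manifest uses paths relative to its own directory, so the
  # fixture is byte-identical wherever it is written (and relocatable);
  # readCohort() resolves them against the manifest's location
  diskManifest <- manifest
  diskManifest$vcf_path <- basename(vcfPaths)
  diskManifest$depth_path <- basename(depthPaths)
  write.table(diskManifest, manifestPath, sep = "\t", quote = FALSE,
              row.names = FALSE)

  files <- c(catTsv, catVcf, vcfPaths, depthPaths, bedPath, annPath,
             truthPath, manifestPath)
  sums <- tools::md5sum(files)
  checkPath <- file.path(outdir, "MANIFEST.txt")
  writeLines(sprintf("%s  %s", sums, basename(files)), checkPath)

  invisible(list(dir = outdir,
                 files = data.frame(path = files, md5 = unname(sums)),
                 manifest = manifest, truth = truth,
                 catalogue = catTsv, catalogueVcf = catVcf,
                 bed = bedPath, annotations = annPath))
}
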