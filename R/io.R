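#' Read a VCF into a GenotypeData object
#'
#' Parses GT fields of a VCF v4.2 (through vcfR) into a minor-allele dosage
#' matrix. Loci are oriented so that the dosage counts the minor allele; a
#' 50/50 frequency tie keeps the ALT allele as the counted one. Missing
#' genotypes (`./.` or `.`) become `NA`. Positions stay 1-based as in the
#' file. Non-biallelic records are skipped with a single warning giving the
#' count; records with an inconsistent number of columns raise a parse error
#' with the offending line number.
#'
#' @param path VCF file (plain text).
#' @return A [GenotypeData-class].
#' @export
readVCF <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF (no #CHROM header line): ", path)
  nField <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- seq(hdr[1] + 1L, length.out = length(lines) - hdr[1])
  if (length(body)) {
    cnt <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[cnt != nField]
    if (length(bad))
      stop("malformed VCF at line ", bad[1], " of ", path, ": expected ",
           nField, " fields, found ", cnt[match(bad[1], body)])
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- is.na(alt) | grepl(",", alt, fixed = TRUE)
  if (any(multi))
    warning(sum(multi), " non-biallelic record(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (!nrow(fix)) stop("no biallelic records in ", path)

  gtNorm <- gsub("|", "/", gt, fixed = TRUE)
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "./." = NA_integer_, "." = NA_integer_, "./0" = NA_integer_,
           "0/." = NA_integer_, "./1" = NA_integer_, "1/." = NA_integer_)
  dos <- matrix(lut[gtNorm], nrow(gtNorm), ncol(gtNorm))
  unknown <- !is.na(gtNorm) & !(gtNorm %in% names(lut))
  if (any(unknown))
    warning(sum(unknown), " unparseable GT value(s) set to missing")
  ids <- fix[, "ID"]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix[noId, "CHROM"], "_", fix[noId, "POS"])
  map <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  dosage <- t(dos)
  dimnames(dosage) <- list(colnames(gt), ids)
  GenotypeData(dosage, map, orient = TRUE)
}

#' Quality-control configuration
#'
#' Thresholds follow the program's filtering rules and are strict
#' inequalities: samples and loci with missingness strictly greater than the
#' maximum are dropped, loci with MAF strictly below the minimum are dropped
#' (so exactly 10% missing or exactly 1% MAF is retained).
#'
#' @param maxMissingSample,maxMissingLocus,minMaf fractions in \[0, 1\]
#'   (defaults 0.10, 0.10, 0.01).
#' @return list of class `QCConfig`.
#' @export
qcConfig <- function(maxMissingSample = 0.10, maxMissingLocus = 0.10,
                     minMaf = 0.01) {
  cfg <- list(maxMissingSample = maxMissingSample,
              maxMissingLocus = maxMissingLocus, minMaf = minMaf)
  if (any(unlist(cfg) < 0 | unlist(cfg) > 1))
    stop("QCConfig thresholds must lie in [0, 1]")
  class(cfg) <- "QCConfig"
  cfg
}

#' Apply missingness and MAF filters
#'
#' Filtering order is fixed: (1) samples with missingness > threshold, (2)
#' loci with missingness > threshold computed on surviving samples, (3) MAF
#' recomputed on surviving samples and loci below the minimum dropped. The
#' order matters on unbalanced missingness patterns and is therefore part of
#' the contract. The operation is idempotent.
#'
#' @param g a [GenotypeData-class].
#' @param cfg a [qcConfig()].
#' @return list with `genotypes` (filtered [GenotypeData-class]) and
#'   `report` (class `QCReport`: `samplesRemoved`, `lociRemoved` by reason,
#'   `lociRetained`, `lociInput`).
#' @export
applyQC <- function(g, cfg = qcConfig()) {
  stopifnot(inherits(cfg, "QCConfig"))
  d <- dosageMatrix(g)
  if (!nrow(d) || !ncol(d)) stop("empty genotype matrix")
  sampleMiss <- rowMeans(is.na(d))
  dropSamp <- sampleMiss > cfg$maxMissingSample
  if (all(dropSamp))
    stop("QC removed every sample (all exceed ",
         100 * cfg$maxMissingSample, "% missingness)")
  d2 <- d[!dropSamp, , drop = FALSE]
  locusMiss <- colMeans(is.na(d2))
  dropMiss <- locusMiss > cfg$maxMissingLocus
  d3 <- d2[, !dropMiss, drop = FALSE]
  freq <- colMeans(d3, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0  # entirely-missing locus that survived the filter
  dropMaf <- maf < cfg$minMaf
  keepLoci <- colnames(d3)[!dropMaf]

  report <- list(
    samplesRemoved = rownames(d)[dropSamp],
    lociRemoved = list(missing = colnames(d2)[dropMiss],
                       maf = colnames(d3)[dropMaf]),
    lociRetained = length(keepLoci),
    lociInput = ncol(d))
  class(report) <- "QCReport"

  keepMap <- markerMap(g)
  keepMap <- keepMap[match(keepLoci, keepMap$snp), , drop = FALSE]
  out <- GenotypeData(
    d3[, keepLoci, drop = FALSE],
    data.frame(chrom = keepMap$chrom, pos = keepMap$pos, ref = keepMap$ref,
               alt = keepMap$alt, counted = keepMap$counted,
               stringsAsFactors = FALSE),
    orient = TRUE)
  list(genotypes = out, report = report)
}

#' Per-window SNP density
#'
#' Counts SNPs in non-overlapping half-open windows `[start, start + window)`
#' anchored at position 1 on each chromosome. Counts sum to the total SNP
#' number. The genome-wide mean density per Mb is attached as attribute
#' `meanPerMb`.
#'
#' @param g a [GenotypeData-class].
#' @param windowBp window size in bp (default 1e6).
#' @param chromLengths optional named vector of chromosome lengths; windows
#'   then tile the full length (chromosomes without SNPs get zero-count
#'   windows).
#' @return data.frame (`chromosome`, `window_start`, `count`).
#' @export
snpDensity <- function(g, windowBp = 1e6, chromLengths = NULL) {
  if (windowBp <= 0) stop("windowBp must be positive")
  map <- markerMap(g)
  chroms <- if (is.null(chromLengths)) unique(map$chrom)
            else names(chromLengths)
  rows <- lapply(chroms, function(ch) {
    pos <- map$pos[map$chrom == ch]
    len <- if (!is.null(chromLengths)) chromLengths[[ch]]
           else if (length(pos)) max(pos) else 0
    nWin <- max(ceiling(len / windowBp), if (length(pos)) 1L else 0L)
    if (nWin == 0L) return(NULL)
    win <- (pos - 1) %/% windowBp + 1L
    counts <- tabulate(win, nbins = nWin)
    data.frame(chromosome = ch,
               window_start = (seq_len(nWin) - 1L) * windowBp + 1,
               count = counts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chromosome = character(), window_start = numeric(),
                      count = integer())
  attr(out, "meanPerMb") <- if (nrow(out))
    sum(out$count) / (nrow(out) * windowBp / 1e6) else NA_real_
  out
}

#' Mean-impute missing dosages
#'
#' Replaces each missing entry by the locus mean dosage over observed
#' samples. Intended for post-QC matrices feeding the GRM and the
#' association scan; a locus with no observed genotype is an error (QC
#' should have removed it).
#'
#' @param g a [GenotypeData-class] or a samples x SNPs dosage matrix.
#' @return complete numeric samples x SNPs matrix.
#' @export
meanImpute <- function(g) {
  d <- if (is.matrix(g)) g else dosageMatrix(g)
  storage.mode(d) <- "double"
  miss <- is.na(d)
  if (!any(miss)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  bad <- !is.finite(mu)
  if (any(bad))
    stop("locus with no observed genotypes (run QC first): ",
         paste(head(colnames(d)[bad]), collapse = ", "))
  idx <- which(miss, arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  d
}
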