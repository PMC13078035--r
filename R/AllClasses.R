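#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats cor cor.test lm aov anova optimize pchisq qchisq pnorm
#'   rnorm runif rbinom sd var median coef model.matrix predict p.adjust
#'   setNames complete.cases t.test pt resid fitted as.formula quantile
#'   aggregate
#' @importFrom utils read.table write.table packageVersion head tail
NULL

#' GenotypeData: accessions-by-SNP minor-allele dosage container
#'
#' Thin extension of [SummarizedExperiment::RangedSummarizedExperiment-class]
#' holding a single `"dosage"` assay (SNPs in rows, accessions in columns;
#' values 0/1/2 counts of the minor allele, `NA` for missing genotypes).
#' Marker coordinates live in `rowRanges()` with metadata columns `ref`,
#' `alt`, `counted` (the allele the dosage counts, i.e. the minor allele)
#' and `maf`.
#'
#' Rows are guaranteed sorted by (chromosome, position) and minor-allele
#' oriented (`maf <= 0.5`); the constructor enforces both.
#'
#' @seealso [GenotypeData()], [dosageMatrix()], [markerMap()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    ok <- d[!is.na(d)]
    if (length(ok) && !all(ok %in% 0:2))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("ref", "alt", "counted", "maf")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData needs columns:", paste(need, collapse = ", ")))
  else if (any(rd$maf > 0.5 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "maf must not exceed 0.5 after minor-allele orientation")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosages numeric matrix, accessions x SNPs, values 0/1/2/NA. Rownames
#'   are accession ids, colnames SNP ids (generated when absent).
#' @param map data.frame with one row per SNP: columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`. Optional column `counted`; when absent the
#'   counted allele is taken to be `alt` before orientation.
#' @param orient flip loci whose counted-allele frequency exceeds 0.5 so that
#'   dosages count the minor allele (ties kept as-is, i.e. broken toward the
#'   allele already counted). Default `TRUE`.
#'
#' @return A [GenotypeData-class] object sorted by (chromosome, position).
#' @examples
#' d <- matrix(c(0, 1, 2, 2, 2, 0), nrow = 3,
#'             dimnames = list(paste0("acc", 1:3), c("s1", "s2")))
#' map <- data.frame(chrom = "Chr01", pos = c(100L, 200L), ref = "A", alt = "T")
#' g <- GenotypeData(d, map)
#' snpMAF(g)
#' @export
GenotypeData <- function(dosages, map, orient = TRUE) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(map) == ncol(dosages))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("acc", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0(map$chrom, "_", map$pos)
  counted <- if ("counted" %in% names(map)) map$counted else map$alt

  freq <- colMeans(dosages, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- NA_real_
  if (orient) {
    # ties (freq exactly 0.5) are canonically counted on the ALT allele
    flip <- !is.na(freq) &
      (freq > 0.5 | (freq == 0.5 & counted != map$alt))
    if (any(flip)) {
      dosages[, flip] <- 2 - dosages[, flip]
      other <- ifelse(counted == map$alt, map$ref, map$alt)
      counted[flip] <- other[flip]
      freq[flip] <- 1 - freq[flip]
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = map$chrom,
    ranges = IRanges::IRanges(start = map$pos, width = 1L),
    ref = map$ref, alt = map$alt, counted = counted, maf = unname(freq))
  names(gr) <- colnames(dosages)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosages)), rowRanges = gr)
  se <- GenomicRanges::sort(se)
  methods::new("GenotypeData", se)
}

#' Genomic relationship matrix (VanRaden)
#'
#' Holds the realized additive relationship matrix
#' \eqn{G = ZZ'/2\sum p_i(1-p_i)} where Z is the allele-frequency-centred
#' dosage matrix, together with its scaling denominator and the diagonal
#' blend added for invertibility.
#'
#' @slot matrix symmetric accessions x accessions relationship matrix.
#' @slot sampleIds accession ids (also the dimnames of `matrix`).
#' @slot denominator the VanRaden scaling \eqn{2\sum p_i(1-p_i)}.
#' @slot blendEpsilon ridge added to the diagonal (0 for none).
#' @seealso [buildGRM()]
#' @export
setClass("GRM", representation(
  matrix = "matrix", sampleIds = "character",
  denominator = "numeric", blendEpsilon = "numeric"))

setValidity("GRM", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  else if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
  if (length(object@sampleIds) != nrow(m))
    msg <- c(msg, "sampleIds length must match matrix dimension")
  if (object@denominator <= 0) msg <- c(msg, "denominator must be positive")
  if (length(msg)) msg else TRUE
})

#' GBLUP model fit
#'
#' REML variance components and the mixed-model-equation solution of the
#' GBLUP model \eqn{y = Xb + Zu + e}, \eqn{u \sim N(0, G\sigma^2_a)}.
#' `gebv` covers every accession in the relationship matrix, including
#' candidates without phenotypes.
#'
#' @slot sigma2a additive genetic variance.
#' @slot sigma2e residual variance.
#' @slot k variance ratio \eqn{\sigma^2_e/\sigma^2_a} entering the MME.
#' @slot h2Narrow narrow-sense heritability \eqn{\sigma^2_a/(\sigma^2_a+\sigma^2_e)}.
#' @slot fixedEffects fixed-effect solutions \eqn{\hat b}.
#' @slot gebv named vector of genomic estimated breeding values \eqn{\hat u}.
#' @slot phenotyped named logical: did the accession contribute a phenotype.
#' @slot boundary TRUE when a variance component was clamped at zero.
#' @slot blendEpsilon diagonal blend inherited from the GRM.
#' @seealso [fitGBLUP()]
#' @export
setClass("GBLUPFit", representation(
  sigma2a = "numeric", sigma2e = "numeric", k = "numeric",
  h2Narrow = "numeric", fixedEffects = "numeric", gebv = "numeric",
  phenotyped = "logical", boundary = "logical", blendEpsilon = "numeric"))

setValidity("GBLUPFit", function(object) {
  msg <- character()
  if (object@sigma2a < 0 || object@sigma2e < 0)
    msg <- c(msg, "variance components must be non-negative")
  if (object@h2Narrow < -1e-9 || object@h2Narrow > 1 + 1e-9)
    msg <- c(msg, "h2Narrow must lie in [0, 1]")
  if (length(object@gebv) != length(object@phenotyped))
    msg <- c(msg, "gebv and phenotyped must have equal length")
  if (length(msg)) msg else TRUE
})
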