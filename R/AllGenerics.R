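#' Accessors for genotype and model containers
#'
#' `dosageMatrix()` returns the accessions x SNPs minor-allele dosage matrix
#' (the transpose of the stored assay, which keeps SNPs in rows per
#' Bioconductor convention). `markerMap()` returns the per-SNP map as a
#' data.frame (`snp`, `chrom`, `pos`, `ref`, `alt`, `counted`, `maf`).
#' `snpMAF()` returns the per-SNP minor allele frequency, `sampleIds()` the
#' accession ids. `grmMatrix()` extracts the dense relationship matrix of a
#' [GRM-class]; `gebv()` and `narrowH2()` extract breeding values and
#' narrow-sense heritability from a [GBLUPFit-class].
#'
#' @param x a [GenotypeData-class], [GRM-class] or [GBLUPFit-class] object.
#' @return See details; plain base-R vectors, matrices and data.frames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname accessors
#' @export
setGeneric("snpMAF", function(x) standardGeneric("snpMAF"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname accessors
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))

#' @rdname accessors
#' @export
setGeneric("narrowH2", function(x) standardGeneric("narrowH2"))

#' @rdname accessors
#' @export
setMethod("dosageMatrix", "GenotypeData", function(x)
  t(SummarizedExperiment::assay(x, "dosage")))

#' @rdname accessors
#' @export
setMethod("markerMap", "GenotypeData", function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  data.frame(
    snp = names(gr),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    ref = gr$ref, alt = gr$alt, counted = gr$counted, maf = gr$maf,
    row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("snpMAF", "GenotypeData", function(x)
  setNames(SummarizedExperiment::rowData(x)$maf, rownames(x)))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeData", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("grmMatrix", "GRM", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("sampleIds", "GRM", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("gebv", "GBLUPFit", function(x) x@gebv)

#' @rdname accessors
#' @export
setMethod("narrowH2", "GBLUPFit", function(x) x@h2Narrow)

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", ncol(object), "accessions x", nrow(object), "SNPs\n")
  m <- SummarizedExperiment::rowData(object)$maf
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("  chromosomes: %d; MAF range: %.3f-%.3f; missing: %.2f%%\n",
              length(unique(as.character(GenomicRanges::seqnames(
                SummarizedExperiment::rowRanges(object))))),
              min(m, na.rm = TRUE), max(m, na.rm = TRUE),
              100 * mean(is.na(d))))
})

setMethod("show", "GRM", function(object) {
  cat("VanRaden GRM:", nrow(object@matrix), "accessions; mean diagonal",
      sprintf("%.3f", mean(diag(object@matrix))),
      "; denominator", sprintf("%.2f", object@denominator),
      "; blend", format(object@blendEpsilon), "\n")
})

setMethod("show", "GBLUPFit", function(object) {
  cat(sprintf(
    "GBLUP fit: sigma2_a = %.4f, sigma2_e = %.4f, k = %.4f, h2 = %.4f\n",
    object@sigma2a, object@sigma2e, object@k, object@h2Narrow))
  cat(sprintf("  %d accessions (%d phenotyped)%s\n", length(object@gebv),
              sum(object@phenotyped),
              if (object@boundary) "; boundary variance estimate" else ""))
})
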