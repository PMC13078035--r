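#' Simulation configuration for the synthetic breeding population
#'
#' Bundles and validates every knob of the founder-mosaic genotype simulator
#' and the multi-environment phenotype generator. Defaults reproduce the
#' structure of the breeding panel the package targets: 169 accessions over
#' 20 chromosomes, a bimodal major-gene quality trait (two recessive
#' major-effect loci, broad-sense heritability ~0.96) and a near-normal
#' polygenic yield trait (~0.45), measured in 4 environments x 3 replicates
#' of an RCBD, with near-zero between-trait correlation.
#'
#' @param nAccessions number of accessions (default 169).
#' @param nChromosomes number of chromosomes (default 20).
#' @param snpsPerChromosome SNPs simulated per chromosome (default 100; a
#'   desk-scale stand-in for resequencing densities).
#' @param chromosomeLengthBp chromosome length in bp (default 2e6).
#' @param mafRange target minor-allele-frequency range, ordered pair in
#'   (0, 0.5] (default c(0.1, 0.5)).
#' @param nFounders number of founder haplotypes the population mosaics are
#'   copied from; must be >= 2 (default 16).
#' @param blockLengthBp LD block length in bp: founder segments are copied in
#'   blocks of this size, so r2 is high within a block and decays to the
#'   finite-sample floor between blocks (default 1e5).
#' @param blockMutationRate per-founder per-SNP probability that a SNP allele
#'   deviates from its block haplotype label; 0 gives perfect within-block LD
#'   (default 0.02).
#' @param majorQtl data.frame (chrom, pos, effect, mode) of major-effect QTL
#'   for trait 1; mode is "recessive" (effect only for the minor-allele
#'   homozygote) or "additive". Default: two recessive loci on Chr09/Chr19.
#' @param nMinorQtl number of small-effect additive QTL per trait (default 30).
#' @param minorEffectSd SD of minor-QTL allele effects, one per trait
#'   (default c(1, 1)).
#' @param h2Trait1,h2Trait2 target broad-sense heritabilities under the
#'   multi-environment formula (defaults 0.96 and 0.45); must be in (0, 1].
#' @param gxeVarianceFraction genotype-by-environment variance as a fraction
#'   of genetic variance (default 0.008).
#' @param envVarianceFraction,repVarianceFraction environment and
#'   replicate-within-environment effect variances as fractions of genetic
#'   variance (defaults 0.25 and 0.01); free parameters of the design.
#' @param nEnvironments,nReplicates trial dimensions (defaults 4 and 3).
#' @param traitCorrelationTarget target genetic correlation between the two
#'   traits; only 0 (independent QTL sets) is implemented (default 0).
#' @param traitNames,traitMeans names and grand means of the two traits
#'   (defaults c("OAC", "SPP"), c(65, 38)).
#' @param missingRate uniform genotype missingness injected into the emitted
#'   matrix to exercise QC (default 0.02).
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#'
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(nAccessions = 169L, nChromosomes = 20L,
                      snpsPerChromosome = 100L, chromosomeLengthBp = 2e6,
                      mafRange = c(0.1, 0.5), nFounders = 16L,
                      blockLengthBp = 1e5, blockMutationRate = 0.02,
                      majorQtl = data.frame(
                        chrom = c("Chr09", "Chr19"), pos = c(1e6, 1e6),
                        effect = c(10, 8), mode = "recessive",
                        stringsAsFactors = FALSE),
                      nMinorQtl = 30L, minorEffectSd = c(1, 1),
                      h2Trait1 = 0.96, h2Trait2 = 0.45,
                      gxeVarianceFraction = 0.008,
                      envVarianceFraction = 0.25, repVarianceFraction = 0.01,
                      nEnvironments = 4L, nReplicates = 3L,
                      traitCorrelationTarget = 0,
                      traitNames = c("OAC", "SPP"), traitMeans = c(65, 38),
                      missingRate = 0.02, seed = 1L) {
  cfg <- list(nAccessions = as.integer(nAccessions),
              nChromosomes = as.integer(nChromosomes),
              snpsPerChromosome = as.integer(snpsPerChromosome),
              chromosomeLengthBp = as.numeric(chromosomeLengthBp),
              mafRange = as.numeric(mafRange),
              nFounders = as.integer(nFounders),
              blockLengthBp = as.numeric(blockLengthBp),
              blockMutationRate = as.numeric(blockMutationRate),
              majorQtl = majorQtl, nMinorQtl = as.integer(nMinorQtl),
              minorEffectSd = as.numeric(minorEffectSd),
              h2Trait1 = as.numeric(h2Trait1), h2Trait2 = as.numeric(h2Trait2),
              gxeVarianceFraction = as.numeric(gxeVarianceFraction),
              envVarianceFraction = as.numeric(envVarianceFraction),
              repVarianceFraction = as.numeric(repVarianceFraction),
              nEnvironments = as.integer(nEnvironments),
              nReplicates = as.integer(nReplicates),
              traitCorrelationTarget = as.numeric(traitCorrelationTarget),
              traitNames = as.character(traitNames),
              traitMeans = as.numeric(traitMeans),
              missingRate = as.numeric(missingRate), seed = as.integer(seed))
  counts <- c("nAccessions", "nChromosomes", "snpsPerChromosome",
              "chromosomeLengthBp", "blockLengthBp", "nEnvironments",
              "nReplicates")
  for (f in counts)
    if (cfg[[f]] <= 0) stop("invalid SimConfig: ", f, " must be > 0")
  if (cfg$nFounders < 2L)
    stop("invalid SimConfig: nFounders must be at least 2")
  if (length(cfg$mafRange) != 2 || cfg$mafRange[1] > cfg$mafRange[2] ||
      cfg$mafRange[1] <= 0 || cfg$mafRange[2] > 0.5)
    stop("invalid SimConfig: mafRange must be an ordered pair in (0, 0.5]")
  for (f in c("h2Trait1", "h2Trait2"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop("invalid SimConfig: ", f, " must be in (0, 1]")
  for (f in c("gxeVarianceFraction", "missingRate", "blockMutationRate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid SimConfig: ", f, " must be in [0, 1]")
  if (cfg$nMinorQtl < 0) stop("invalid SimConfig: nMinorQtl must be >= 0")
  class(cfg) <- "SimConfig"
  cfg
}

.chromLabels <- function(n) sprintf("Chr%02d", seq_len(n))

#' Simulate genotypes by founder-mosaic copying
#'
#' Generates biallelic 0/1/2 dosages for `nAccessions` diploid accessions.
#' Each chromosome is partitioned into consecutive blocks of
#' `blockLengthBp`; within a block each founder carries one of two block
#' haplotype labels (label frequency drawn from `mafRange`), and individual
#' SNP alleles deviate from the label with probability `blockMutationRate`.
#' Each of an accession's two gametes copies a uniformly chosen founder per
#' block, so adjacent SNPs show high r2 that collapses to the finite-sample
#' floor across block boundaries -- the block structure that LD-based
#' tag-SNP selection assumes.
#'
#' Major-QTL positions in `config$majorQtl` are mapped to the nearest
#' simulated SNP with MAF >= 0.3 on the stated chromosome (so a recessive
#' minor-homozygote class of usable size exists); minor QTL are drawn
#' uniformly from the remaining SNPs. True breeding values are computed on
#' the complete matrix before missingness is injected.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `genotypes` (a [GenotypeData-class]) and
#'   `truth` (class `SimTruth`: `trueBreedingValues` accessions x traits,
#'   `qtlEffects` data.frame, `founderHaplotypes`, `blockAssignments` named
#'   per-SNP block ids).
#' @examples
#' sim <- simulateGenotypes(simConfig(nAccessions = 50, nChromosomes = 2,
#'                                    snpsPerChromosome = 20, seed = 7))
#' dim(dosageMatrix(sim$genotypes))
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nAcc <- config$nAccessions
  nGam <- 2L * nAcc
  nF <- config$nFounders
  chroms <- .chromLabels(config$nChromosomes)
  S <- config$snpsPerChromosome

  dosList <- vector("list", config$nChromosomes)
  mapList <- vector("list", config$nChromosomes)
  foundList <- vector("list", config$nChromosomes)
  blockList <- vector("list", config$nChromosomes)
  blockOffset <- 0L

  for (ci in seq_along(chroms)) {
    pos <- sort(sample.int(config$chromosomeLengthBp, S))
    blockIdx <- as.integer((pos - 1) %/% config$blockLengthBp) + 1L
    nBlocks <- max(blockIdx)
    # founder alleles: block label per founder, flipped per SNP at the
    # mutation rate
    founderAll <- matrix(0L, nF, S)
    for (b in unique(blockIdx)) {
      idx <- which(blockIdx == b)
      q <- runif(1, config$mafRange[1], config$mafRange[2])
      k <- min(max(as.integer(round(q * nF)), 1L), nF - 1L)
      lab <- integer(nF)
      lab[sample.int(nF, k)] <- 1L
      block <- matrix(rep(lab, length(idx)), nF, length(idx))
      if (config$blockMutationRate > 0) {
        flip <- matrix(rbinom(nF * length(idx), 1L,
                              config$blockMutationRate), nF)
        block <- abs(block - flip)
      }
      founderAll[, idx] <- block
    }
    # mosaic gametes: one founder choice per gamete per block
    choice <- matrix(sample.int(nF, nGam * nBlocks, replace = TRUE),
                     nGam, nBlocks)
    founderAtSnp <- choice[, blockIdx, drop = FALSE]
    hap <- matrix(founderAll[cbind(as.vector(founderAtSnp),
                                   rep(seq_len(S), each = nGam))], nGam, S)
    dos <- hap[seq(1, nGam, 2), , drop = FALSE] +
      hap[seq(2, nGam, 2), , drop = FALSE]

    snpIds <- paste0(chroms[ci], "_", pos)
    colnames(dos) <- snpIds
    dosList[[ci]] <- dos
    nt <- c("A", "C", "G", "T")
    refIdx <- sample.int(4, S, replace = TRUE)
    altIdx <- ((refIdx + sample.int(3, S, replace = TRUE) - 1L) %% 4L) + 1L
    mapList[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                                ref = nt[refIdx], alt = nt[altIdx],
                                stringsAsFactors = FALSE)
    colnames(founderAll) <- snpIds
    foundList[[ci]] <- founderAll
    blockList[[ci]] <- setNames(blockIdx + blockOffset, snpIds)
    blockOffset <- blockOffset + nBlocks
  }

  dosage <- do.call(cbind, dosList)
  rownames(dosage) <- sprintf("acc%03d", seq_len(nAcc))
  map <- do.call(rbind, mapList)
  blockAssign <- do.call(c, blockList)
  founderHaps <- do.call(cbind, foundList)

  # orient to the minor allele before truth is computed, so recessive QTL
  # effects refer to the minor-homozygote class of the emitted data
  freq <- colMeans(dosage) / 2
  flip <- freq > 0.5
  dosage[, flip] <- 2L - dosage[, flip]
  counted <- ifelse(flip, map$ref, map$alt)
  maf <- ifelse(flip, 1 - freq, freq)

  truth <- .assignQtl(dosage, map, maf, config)
  truth$founderHaplotypes <- founderHaps
  truth$blockAssignments <- blockAssign
  class(truth) <- "SimTruth"

  if (config$missingRate > 0) {
    miss <- matrix(runif(length(dosage)) < config$missingRate, nrow(dosage))
    dosage[miss] <- NA_integer_
  }
  map$counted <- counted
  g <- GenotypeData(dosage, map, orient = TRUE)
  list(genotypes = g, truth = truth)
}

# map major QTL to nearest common SNP, draw minor QTL, accumulate true
# breeding values per trait
.assignQtl <- function(dosage, map, maf, config) {
  snpIds <- colnames(dosage)
  nAcc <- nrow(dosage)
  qtlRows <- list()
  tbv <- matrix(0, nAcc, 2,
                dimnames = list(rownames(dosage), config$traitNames))
  majorIdx <- integer(0)
  mq <- config$majorQtl
  if (!is.null(mq) && nrow(mq) > 0) {
    for (i in seq_len(nrow(mq))) {
      onChrom <- which(map$chrom == mq$chrom[i])
      if (!length(onChrom))
        stop("majorQtl chromosome not simulated: ", mq$chrom[i])
      common <- onChrom[maf[onChrom] >= 0.3]
      pool <- if (length(common)) common else onChrom
      j <- pool[which.min(abs(map$pos[pool] - mq$pos[i]))]
      majorIdx <- c(majorIdx, j)
      contrib <- if (identical(mq$mode[i], "additive"))
        mq$effect[i] * dosage[, j] else mq$effect[i] * (dosage[, j] == 2L)
      tbv[, 1] <- tbv[, 1] + contrib
      qtlRows[[length(qtlRows) + 1L]] <- data.frame(
        trait = config$traitNames[1], snp = snpIds[j], chrom = map$chrom[j],
        pos = map$pos[j], effect = mq$effect[i], mode = mq$mode[i],
        stringsAsFactors = FALSE)
    }
  }
  avail <- setdiff(seq_along(snpIds), majorIdx)
  for (t in 1:2) {
    nq <- min(config$nMinorQtl, length(avail))
    if (nq > 0) {
      pick <- sample(avail, nq)
      eff <- rnorm(nq, 0, config$minorEffectSd[t])
      tbv[, t] <- tbv[, t] + dosage[, pick, drop = FALSE] %*% eff
      qtlRows[[length(qtlRows) + 1L]] <- data.frame(
        trait = config$traitNames[t], snp = snpIds[pick],
        chrom = map$chrom[pick], pos = map$pos[pick], effect = eff,
        mode = "additive", stringsAsFactors = FALSE)
      avail <- setdiff(avail, pick)
    }
  }
  list(trueBreedingValues = tbv,
       qtlEffects = do.call(rbind, qtlRows))
}

#' Simulate multi-environment RCBD phenotypes
#'
#' Each observation is grand mean + environment effect + replicate-within-
#' environment effect + centred genetic value + GxE draw + residual. The GxE
#' and residual variances are scaled from the realized genetic variance so
#' that the multi-environment broad-sense heritability
#' \eqn{\sigma^2_g/(\sigma^2_g + \sigma^2_{ge}/n + \sigma^2_e/nr)} equals the
#' configured target in expectation. Environment and replicate effects are
#' drawn once per simulation and recorded in the attributes (fixed-in-truth,
#' so BLUE recovery can be checked exactly).
#'
#' @param genotypes,truth output of [simulateGenotypes()].
#' @param config the same [simConfig()].
#' @return long-format data.frame (`accession`, `environment`, `replicate`,
#'   `trait`, `value`) with attributes `envEffects`, `repEffects` and
#'   `varianceComponents` (per-trait list of sigma2g/sigma2ge/sigma2eps).
#' @export
simulatePhenotypes <- function(genotypes, truth, config) {
  stopifnot(inherits(config, "SimConfig"), inherits(truth, "SimTruth"))
  acc <- sampleIds(genotypes)
  if (!all(acc %in% rownames(truth$trueBreedingValues)))
    stop("truth is missing breeding values for accession(s): ",
         paste(head(setdiff(acc, rownames(truth$trueBreedingValues))),
               collapse = ", "))
  set.seed(config$seed + 1L)
  nAcc <- length(acc)
  nE <- config$nEnvironments
  nR <- config$nReplicates
  envs <- sprintf("E%d", seq_len(nE))
  reps <- sprintf("R%d", seq_len(nR))

  out <- vector("list", 2L)
  envEff <- repEff <- vc <- list()
  h2s <- c(config$h2Trait1, config$h2Trait2)
  for (t in 1:2) {
    tn <- config$traitNames[t]
    gRaw <- truth$trueBreedingValues[acc, t]
    gc <- gRaw - mean(gRaw)
    s2g <- var(gc)
    fge <- config$gxeVarianceFraction
    s2ge <- fge * s2g
    s2eps <- nE * nR * s2g * (1 / h2s[t] - 1 - fge / nE)
    if (s2eps < -1e-9)
      stop("infeasible heritability target for ", tn,
           ": gxeVarianceFraction too large for h2 = ", h2s[t])
    s2eps <- max(s2eps, 0)
    e <- rnorm(nE, 0, sqrt(config$envVarianceFraction * s2g))
    r <- matrix(rnorm(nE * nR, 0, sqrt(config$repVarianceFraction * s2g)),
                nE, nR, dimnames = list(envs, reps))
    ge <- matrix(rnorm(nAcc * nE, 0, sqrt(s2ge)), nAcc, nE,
                 dimnames = list(acc, envs))
    grid <- expand.grid(accession = acc, environment = envs,
                        replicate = reps, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    ei <- match(grid$environment, envs)
    val <- config$traitMeans[t] + e[ei] +
      r[cbind(ei, match(grid$replicate, reps))] +
      gc[grid$accession] + ge[cbind(grid$accession, grid$environment)] +
      rnorm(nrow(grid), 0, sqrt(s2eps))
    grid$trait <- tn
    grid$value <- as.numeric(val)
    out[[t]] <- grid
    envEff[[tn]] <- setNames(e, envs)
    repEff[[tn]] <- r
    vc[[tn]] <- list(sigma2g = s2g, sigma2ge = s2ge, sigma2eps = s2eps)
  }
  pheno <- do.call(rbind, out)
  rownames(pheno) <- NULL
  attr(pheno, "envEffects") <- envEff
  attr(pheno, "repEffects") <- repEff
  attr(pheno, "varianceComponents") <- vc
  pheno
}

#' Write a simulated data set to disk as plain-text fixtures
#'
#' Emits a VCF v4.2 (GT field only, missing genotypes as `./.`), a
#' tab-separated long-format phenotype table and tab-separated truth tables
#' (breeding values, QTL effects, per-SNP block assignments). The VCF
#' round-trips losslessly through [readVCF()].
#'
#' @param genotypes a [GenotypeData-class].
#' @param phenotypes long-format phenotype data.frame (may be NULL).
#' @param truth a `SimTruth` (may be NULL).
#' @param dir output directory, created if needed.
#' @return invisible named character vector of the files written.
#' @export
writeFixture <- function(genotypes, phenotypes, truth, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory: ", dir)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"))
  writeVCF(genotypes, paths["vcf"])
  if (!is.null(phenotypes)) {
    paths["phenotypes"] <- file.path(dir, "phenotypes.tsv")
    write.table(phenotypes, paths["phenotypes"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    paths["truth_tbv"] <- file.path(dir, "truth_breeding_values.tsv")
    tbv <- data.frame(accession = rownames(truth$trueBreedingValues),
                      truth$trueBreedingValues, check.names = FALSE)
    write.table(tbv, paths["truth_tbv"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths["truth_qtl"] <- file.path(dir, "truth_qtl.tsv")
    write.table(truth$qtlEffects, paths["truth_qtl"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths["truth_blocks"] <- file.path(dir, "truth_blocks.tsv")
    write.table(data.frame(snp = names(truth$blockAssignments),
                           block = unname(truth$blockAssignments)),
                paths["truth_blocks"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

#' Write genotypes as VCF v4.2 (GT only)
#'
#' @param genotypes a [GenotypeData-class].
#' @param path output file.
#' @return invisible `path`.
#' @export
writeVCF <- function(genotypes, path) {
  map <- markerMap(genotypes)
  d <- dosageMatrix(genotypes)
  # dosage counts the minor allele; GT is written relative to REF/ALT
  altCount <- d
  refCounted <- map$counted != map$alt
  if (any(refCounted))
    altCount[, refCounted] <- 2L - altCount[, refCounted]
  gtCode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(altCount)
  gt[ok] <- gtCode[altCount[ok] + 1L]

  chromMax <- tapply(map$pos, map$chrom, max)
  header <- c("##fileformat=VCFv4.2",
              "##source=TagGS",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              sprintf("##contig=<ID=%s,length=%d>", names(chromMax),
                      as.integer(chromMax)),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$snp, map$ref, map$alt, ".", "PASS",
                ".", "GT", apply(gt, 2, paste, collapse = "\t"),
                sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
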