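test_that("configuration is validated", {
  expect_error(simConfig(nFounders = 1), "nFounders")
  expect_error(simConfig(mafRange = c(0.4, 0.2)), "mafRange")
  expect_error(simConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(simConfig(h2Trait1 = 0), "h2Trait1")
  expect_error(simConfig(nEnvironments = 0), "nEnvironments")
})

test_that("a fixed seed reproduces genotypes and phenotypes exactly", {
  cfg <- simConfig(nAccessions = 40, nChromosomes = 2,
                   snpsPerChromosome = 30, majorQtl = majorQtlOn("Chr01"),
                   seed = 5)
  a <- simulateGenotypes(cfg)
  b <- simulateGenotypes(cfg)
  expect_identical(dosageMatrix(a$genotypes), dosageMatrix(b$genotypes))
  expect_identical(markerMap(a$genotypes), markerMap(b$genotypes))
  expect_identical(a$truth$trueBreedingValues, b$truth$trueBreedingValues)
  pa <- simulatePhenotypes(a$genotypes, a$truth, cfg)
  pb <- simulatePhenotypes(b$genotypes, b$truth, cfg)
  expect_identical(pa$value, pb$value)
})

test_that("single-block two-founder limit gives r2 = 1 for every SNP pair", {
  cfg <- simConfig(nAccessions = 100, nChromosomes = 1,
                   snpsPerChromosome = 40, chromosomeLengthBp = 1e6,
                   blockLengthBp = 1e6, nFounders = 2,
                   blockMutationRate = 0, missingRate = 0,
                   majorQtl = majorQtlOn("Chr01"), seed = 2)
  g <- simulateGenotypes(cfg)$genotypes
  d <- dosageMatrix(g)
  poly <- apply(d, 2, var) > 0
  r2 <- cor(d[, poly])^2
  expect_true(all(r2 > 1 - 1e-9))
})

test_that("r2 is high for adjacent SNPs and decays across blocks", {
  cfg <- simConfig(nAccessions = 200, nChromosomes = 4,
                   snpsPerChromosome = 500, chromosomeLengthBp = 2e6,
                   blockLengthBp = 5e4, missingRate = 0,
                   majorQtl = majorQtlOn("Chr01"), seed = 7)
  sim <- simulateGenotypes(cfg)
  d <- dosageMatrix(sim$genotypes)
  map <- markerMap(sim$genotypes)
  adj <- far <- c()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    for (i in seq_len(length(idx) - 1)) {
      j <- i + 1
      if (var(d[, idx[i]]) == 0 || var(d[, idx[j]]) == 0) next
      gap <- pos[j] - pos[i]
      if (gap < cfg$blockLengthBp)
        adj <- c(adj, cor(d[, idx[i]], d[, idx[j]])^2)
    }
    distant <- which(outer(pos, pos, function(a, b) b - a) >
                       10 * cfg$blockLengthBp, arr.ind = TRUE)
    pick <- distant[seq(1, nrow(distant), length.out = min(200,
                                                           nrow(distant))), ,
                    drop = FALSE]
    for (k in seq_len(nrow(pick))) {
      a <- idx[pick[k, 1]]
      b <- idx[pick[k, 2]]
      if (var(d[, a]) == 0 || var(d[, b]) == 0) next
      far <- c(far, cor(d[, a], d[, b])^2)
    }
  }
  expect_gt(mean(adj), mean(far))
  expect_gt(mean(adj), 0.5)
  expect_lt(mean(far), 0.1)
})

test_that("realized MAF tracks the configured range", {
  sim <- panelSim()
  maf <- snpMAF(sim$genotypes)
  lo <- sim$config$mafRange[1]
  expect_true(all(maf <= 0.5 + 1e-9))
  expect_gte(mean(maf >= lo - 0.05), 0.95)
  expect_true(all(maf >= lo - 0.10))
})

test_that("noise-free phenotypes decompose exactly into truth effects", {
  cfg <- simConfig(nAccessions = 30, nChromosomes = 2,
                   snpsPerChromosome = 30, h2Trait1 = 1, h2Trait2 = 1,
                   gxeVarianceFraction = 0, missingRate = 0,
                   majorQtl = majorQtlOn("Chr01"), seed = 8)
  sim <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
  vc <- attr(ph, "varianceComponents")
  env <- attr(ph, "envEffects")
  rep <- attr(ph, "repEffects")
  for (tn in cfg$traitNames) {
    expect_equal(vc[[tn]]$sigma2ge, 0)
    expect_equal(vc[[tn]]$sigma2eps, 0)
    sub <- ph[ph$trait == tn, ]
    gRaw <- sim$truth$trueBreedingValues[, tn]
    gc <- gRaw - mean(gRaw)
    mi <- cfg$traitMeans[match(tn, cfg$traitNames)]
    recon <- mi + env[[tn]][sub$environment] +
      rep[[tn]][cbind(sub$environment, sub$replicate)] + gc[sub$accession]
    expect_equal(sub$value, unname(recon), tolerance = 1e-12)
  }
})

test_that("missing truth for an accession is a consistency error", {
  cfg <- simConfig(nAccessions = 20, nChromosomes = 2,
                   snpsPerChromosome = 20, majorQtl = majorQtlOn("Chr01"),
                   seed = 3)
  sim <- simulateGenotypes(cfg)
  truncated <- sim$truth
  truncated$trueBreedingValues <-
    truncated$trueBreedingValues[-1, , drop = FALSE]
  expect_error(simulatePhenotypes(sim$genotypes, truncated, cfg),
               "missing breeding values")
})

test_that("REML broad-sense heritability recovers the trait-2 target", {
  errs <- vapply(1:20, function(s) {
    cfg <- simConfig(nAccessions = 170, nChromosomes = 4,
                     snpsPerChromosome = 50, nEnvironments = 3,
                     nReplicates = 3, majorQtl = majorQtlOn("Chr01"),
                     missingRate = 0, seed = 100 + s)
    sim <- simulateGenotypes(cfg)
    ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
    h2 <- broadSenseH2(fitMultiEnvModel(ph, "SPP"))
    abs(h2 - 0.45)
  }, numeric(1))
  expect_lt(median(errs), 0.04)
  # the analytic sampling sd of the H2 estimate in this design is ~0.06
  # (sigma_g's CV is ~24% when residual variance dominates), so ~80% of
  # seeds are expected inside +/-0.08; assert coverage is not degraded
  # beyond binomial noise around that expectation
  expect_gte(mean(errs <= 0.08), 0.7)
})

test_that("the two traits are essentially uncorrelated", {
  sim <- panelSim()
  tc <- traitCorrelation(sim$pheno, "OAC", "SPP")
  expect_true(all(abs(tc$r) < 0.2))
})

test_that("single-plot variance bookkeeping matches the configuration", {
  sim <- panelSim()
  vc <- attr(sim$pheno, "varianceComponents")
  for (tn in sim$config$traitNames) {
    v <- vc[[tn]]
    implied <- v$sigma2g / (v$sigma2g + v$sigma2ge + v$sigma2eps)
    slice <- sim$pheno[sim$pheno$trait == tn &
                         sim$pheno$environment == "E1" &
                         sim$pheno$replicate == "R1", ]
    gRaw <- sim$truth$trueBreedingValues[slice$accession, tn]
    ratio <- var(gRaw) / var(slice$value)
    expect_lt(abs(ratio - implied), 0.1)
  }
})

test_that("recessive major-QTL dosage classes differ by the configured effect", {
  cfg <- simConfig(nAccessions = 150, nChromosomes = 2,
                   snpsPerChromosome = 40, nMinorQtl = 0,
                   majorQtl = majorQtlOn("Chr01", effect = 10),
                   missingRate = 0, seed = 6)
  sim <- simulateGenotypes(cfg)
  qtl <- sim$truth$qtlEffects
  qtl <- qtl[qtl$mode == "recessive", ]
  d <- dosageMatrix(sim$genotypes)[, qtl$snp]
  tbv <- sim$truth$trueBreedingValues[, "OAC"]
  expect_equal(mean(tbv[d == 2]) - mean(tbv[d < 2]), qtl$effect,
               tolerance = 1e-12)
  # with polygenic background the class contrast stays near the effect and
  # is overwhelmingly significant
  cfg2 <- simConfig(nAccessions = 150, nChromosomes = 2,
                    snpsPerChromosome = 40, nMinorQtl = 20,
                    majorQtl = majorQtlOn("Chr01", effect = 10),
                    missingRate = 0, seed = 6)
  sim2 <- simulateGenotypes(cfg2)
  q2 <- sim2$truth$qtlEffects
  q2 <- q2[q2$mode == "recessive", ]
  d2 <- dosageMatrix(sim2$genotypes)[, q2$snp]
  tbv2 <- sim2$truth$trueBreedingValues[, "OAC"]
  tt <- t.test(tbv2[d2 == 2], tbv2[d2 < 2])
  expect_lt(tt$p.value, 1e-6)
  expect_lt(abs(diff(rev(tt$estimate)) - q2$effect), 3)
})

test_that("fixtures round-trip and use the ./. missing sentinel", {
  cfg <- simConfig(nAccessions = 50, nChromosomes = 4,
                   snpsPerChromosome = 125, missingRate = 0.05,
                   majorQtl = majorQtlOn("Chr01"), seed = 12)
  sim <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
  dir <- withr::local_tempdir()
  paths <- writeFixture(sim$genotypes, ph, sim$truth, dir)
  expect_true(all(file.exists(paths)))
  vcfText <- readLines(paths["vcf"])
  expect_true(any(grepl("\\./\\.", vcfText)))
  expect_lt(file.size(paths["vcf"]), 5e6)  # 50 x 500 fixture stays small
  g2 <- readVCF(paths["vcf"])
  d1 <- dosageMatrix(sim$genotypes)
  d2 <- dosageMatrix(g2)
  expect_identical(dimnames(d1), dimnames(d2))
  expect_true(all(d1 == d2 | (is.na(d1) & is.na(d2))))
  ph2 <- read.table(paths["phenotypes"], sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  expect_equal(ph2$value, ph$value)
})
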