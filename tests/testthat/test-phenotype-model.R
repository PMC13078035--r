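# Balanced two-way data with known variance components, drawn directly.
balancedPheno <- function(ng, ne, nr, s2g, s2ge, s2e, seed,
                          trait = "T", mu = 10) {
  set.seed(seed)
  gfx <- rnorm(ng, 0, sqrt(s2g))
  gefx <- matrix(rnorm(ng * ne, 0, sqrt(s2ge)), ng, ne)
  dat <- expand.grid(accession = sprintf("g%03d", seq_len(ng)),
                     environment = paste0("E", seq_len(ne)),
                     replicate = paste0("R", seq_len(nr)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(dat$accession, sprintf("g%03d", seq_len(ng)))
  ei <- match(dat$environment, paste0("E", seq_len(ne)))
  dat$trait <- trait
  dat$value <- mu + 0.5 * ei + gfx[gi] + gefx[cbind(gi, ei)] +
    rnorm(nrow(dat), 0, sqrt(s2e))
  attr(dat, "gfx") <- setNames(gfx, sprintf("g%03d", seq_len(ng)))
  dat
}

# expected-mean-squares (method-of-moments) estimator for balanced data
anovaMoments <- function(dat) {
  dat$accession <- factor(dat$accession)
  dat$environment <- factor(dat$environment)
  dat$replicate <- factor(dat$replicate)
  nr <- nlevels(dat$replicate)
  ne <- nlevels(dat$environment)
  tab <- summary(aov(value ~ environment + environment:replicate +
                       accession + environment:accession, data = dat))[[1]]
  ms <- setNames(tab[["Mean Sq"]], trimws(rownames(tab)))
  c(sigma2eps = unname(ms["Residuals"]),
    sigma2ge = unname((ms["environment:accession"] - ms["Residuals"]) / nr),
    sigma2g = unname((ms["accession"] -
                        ms["environment:accession"]) / (ne * nr)))
}

test_that("REML equals the ANOVA moment estimator on balanced data", {
  dat <- balancedPheno(8, 3, 2, s2g = 4, s2ge = 1, s2e = 2, seed = 42)
  vc <- fitMultiEnvModel(dat, "T")
  mm <- anovaMoments(dat)
  expect_equal(vc$sigma2g, mm["sigma2g"], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(vc$sigma2ge, mm["sigma2ge"], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(vc$sigma2eps, mm["sigma2eps"], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("variance components are recovered within 20% at n = 200", {
  rel <- t(vapply(1:20, function(s) {
    dat <- balancedPheno(200, 4, 3, s2g = 4, s2ge = 1, s2e = 2,
                         seed = 500 + s)
    vc <- fitMultiEnvModel(dat, "T")
    abs(c(vc$sigma2g / 4, vc$sigma2ge / 1, vc$sigma2eps / 2) - 1)
  }, numeric(3)))
  expect_true(all(apply(rel, 2, median) < 0.20))
})

test_that("zero-noise data puts GE and residual variance at the boundary", {
  cfg <- simConfig(nAccessions = 40, nChromosomes = 2,
                   snpsPerChromosome = 30, h2Trait1 = 1, h2Trait2 = 1,
                   gxeVarianceFraction = 0, missingRate = 0,
                   majorQtl = majorQtlOn("Chr01"), seed = 3)
  sim <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
  vc <- fitMultiEnvModel(ph, "OAC")
  expect_equal(vc$sigma2ge, 0, tolerance = 1e-6)
  expect_equal(vc$sigma2eps, 0, tolerance = 1e-6)
  expect_true(vc$boundary["sigma2ge"])
  expect_true(vc$boundary["sigma2eps"])
  expect_gt(vc$sigma2g, 0)
})

test_that("degenerate designs are rejected with informative errors", {
  dat <- balancedPheno(5, 2, 2, 1, 0.1, 0.5, seed = 1)
  expect_error(fitMultiEnvModel(dat[dat$environment == "E1", ], "T"),
               "2 environments")
  one <- dat[dat$replicate == "R1", ]
  expect_error(fitMultiEnvModel(one, "T"), "2 replicates")
})

test_that("the heritability formula is exact and monotone", {
  expect_equal(broadSenseH2(list(sigma2g = 1, sigma2ge = 0, sigma2eps = 0,
                                 nEnv = 2, nRep = 3)), 1.0)
  expect_equal(broadSenseH2(list(sigma2g = 1, sigma2ge = 2, sigma2eps = 6,
                                 nEnv = 2, nRep = 3)), 1 / 3)
  expect_error(broadSenseH2(list(sigma2g = 0, sigma2ge = 0, sigma2eps = 0,
                                 nEnv = 2, nRep = 3)), "undefined")
  h2 <- function(g, ge, e, n, r)
    broadSenseH2(list(sigma2g = g, sigma2ge = ge, sigma2eps = e,
                      nEnv = n, nRep = r))
  grid <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(vapply(grid, h2, numeric(1), ge = 1, e = 1,
                              n = 3, r = 3)) > 0))
  expect_true(all(diff(vapply(grid, h2, numeric(1), g = 1, e = 1,
                              n = 3, r = 3)) < 0))
  expect_true(all(diff(vapply(grid, function(e) h2(1, 1, e, 3, 3),
                              numeric(1))) < 0))
  expect_true(all(diff(vapply(2:6, function(n) h2(1, 1, 1, n, 3),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(2:6, function(r) h2(1, 1, 1, 3, r),
                              numeric(1))) > 0))
})

test_that("BLUEs equal genotype means up to a constant on balanced data", {
  dat <- balancedPheno(12, 3, 2, s2g = 4, s2ge = 0.5, s2e = 1, seed = 7)
  b <- computeBLUEs(dat, "T")
  gm <- tapply(dat$value, dat$accession, mean)
  shift <- b$blue - gm[b$accession]
  expect_lt(diff(range(shift)), 1e-9)
  # without noise the BLUEs rank exactly like the true genetic values
  clean <- balancedPheno(12, 3, 2, s2g = 4, s2ge = 0, s2e = 0, seed = 7)
  bc <- computeBLUEs(clean, "T")
  expect_equal(cor(bc$blue, attr(clean, "gfx")[bc$accession],
                   method = "spearman"), 1, tolerance = 1e-9)
})

test_that("single-environment single-replicate BLUEs are the raw values", {
  dat <- data.frame(accession = paste0("g", 1:5), environment = "E1",
                    replicate = "R1", trait = "T",
                    value = c(3, 9, 1, 7, 5), stringsAsFactors = FALSE)
  b <- computeBLUEs(dat, "T")
  expect_equal(b$blue[match(dat$accession, b$accession)], dat$value)
})

test_that("BLUEs track truth on unbalanced high-heritability data", {
  sim <- panelSim()
  ph <- sim$pheno[sim$pheno$trait == "OAC", ]
  set.seed(9)
  ph <- ph[-sample(nrow(ph), round(0.1 * nrow(ph))), ]
  b <- computeBLUEs(ph, "OAC")
  tbv <- sim$truth$trueBreedingValues[b$accession, "OAC"]
  expect_gt(cor(b$blue, tbv), 0.95)
})

test_that("confounded designs raise a rank-deficiency error", {
  dat <- balancedPheno(4, 2, 2, 1, 0.1, 0.5, seed = 2)
  # E2 holds only g001 and g001 appears only in E2: fully confounded
  dat <- dat[!(dat$environment == "E2" & dat$accession != "g001") &
               !(dat$environment == "E1" & dat$accession == "g001"), ]
  expect_error(computeBLUEs(dat, "T"), "rank-deficient")
})

test_that("summaries of a constant trait have zero variance and CV", {
  dat <- data.frame(accession = rep(paste0("g", 1:4), 2),
                    environment = "E1",
                    replicate = rep(c("R1", "R2"), each = 4), trait = "T",
                    value = 5, stringsAsFactors = FALSE)
  ts <- traitSummary(dat, "T")
  expect_equal(ts$variance, 0)
  expect_equal(ts$cv, 0)
  expect_equal(ts$max, ts$min)
})

test_that("GxE mean-square share matches the configured small fraction", {
  sim <- panelSim()
  at <- anovaTable(sim$pheno, "OAC")
  msGE <- at$ms[at$term == "GxE"]
  msG <- at$ms[at$term == "Genotype"]
  vc <- attr(sim$pheno, "varianceComponents")$OAC
  nr <- sim$config$nReplicates
  ne <- sim$config$nEnvironments
  expectedShare <- (vc$sigma2eps + nr * vc$sigma2ge) /
    (vc$sigma2eps + nr * vc$sigma2ge + ne * nr * vc$sigma2g)
  observedShare <- msGE / msG
  expect_lt(observedShare / expectedShare, 2)
  expect_gt(observedShare / expectedShare, 0.5)
  expect_identical(at$term,
                   c("Environment", "Genotype", "Rep(Env)", "GxE",
                     "Residual"))
})

test_that("trait correlations behave on arranged inputs", {
  dat <- data.frame(
    accession = rep(paste0("g", 1:4), 2),
    environment = "E1", replicate = "R1",
    trait = rep(c("A", "B"), each = 4),
    value = c(1, 2, 3, 4, 1, 2, 3, 4), stringsAsFactors = FALSE)
  tc <- traitCorrelation(dat, "A", "B")
  expect_equal(tc$r, 1)
  expect_lt(tc$p, 1e-6)
  orth <- dat
  orth$value[orth$trait == "B"] <- c(1, -1, -1, 1)  # orthogonal to 1:4
  expect_equal(traitCorrelation(orth, "A", "B")$r, 0)
  zv <- dat
  zv$value[zv$trait == "B"] <- 2
  expect_error(traitCorrelation(zv, "A", "B"), "zero variance")
})
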