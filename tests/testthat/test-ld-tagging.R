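ldToy <- function(x, y) {
  d <- cbind(a = x, b = y)
  rownames(d) <- paste0("s", seq_along(x))
  toyGenotypes(d, pos = c(1000L, 2000L))
}

test_that("identical columns give r2 = 1 and D' = 1", {
  g <- ldToy(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2))
  ld <- ldPair(g, "a", "b")
  expect_equal(unname(ld["r2"]), 1)
  expect_equal(unname(ld["dprime"]), 1, tolerance = 1e-6)
})

test_that("an orthogonal equal-frequency pair gives r2 = 0", {
  g <- ldToy(c(0, 0, 2, 2, 0, 0, 2, 2), c(0, 2, 0, 2, 0, 2, 0, 2))
  expect_equal(unname(ldPair(g, "a", "b")["r2"]), 0)
})

test_that("EM D' matches the brute-force likelihood oracle on toys", {
  toys <- list(list(x = c(0, 1, 2, 1, 0, 2), y = c(0, 1, 2, 0, 1, 2)),
               list(x = c(0, 0, 1, 1, 2, 2), y = c(0, 1, 0, 2, 1, 2)),
               list(x = c(2, 1, 0, 0, 1, 1), y = c(2, 2, 0, 0, 0, 1)))
  for (t in toys) {
    g <- ldToy(t$x, t$y)
    ld <- ldPair(g, "a", "b")
    expect_equal(unname(ld["r2"]), cor(t$x, t$y)^2, tolerance = 1e-12)
    expect_equal(unname(ld["dprime"]), bruteForceDprime(t$x, t$y),
                 tolerance = 2e-3)
  }
})

test_that("r2 is symmetric and orientation-invariant; monomorphic errors", {
  set.seed(1)
  x <- sample(0:2, 30, replace = TRUE)
  y <- sample(0:2, 30, replace = TRUE)
  g1 <- ldToy(x, y)
  g2 <- ldToy(y, x)
  g3 <- ldToy(2 - x, y)
  expect_equal(ldPair(g1, "a", "b")["r2"], ldPair(g1, "b", "a")["r2"])
  expect_equal(ldPair(g1, "a", "b")["r2"], ldPair(g2, "a", "b")["r2"])
  expect_equal(ldPair(g1, "a", "b")["r2"], ldPair(g3, "a", "b")["r2"],
               tolerance = 1e-12)
  gm <- ldToy(rep(1, 30), y)
  expect_error(ldPair(gm, "a", "b"), "monomorphic|undefined")
})

test_that("founder blocks are recovered exactly as truth partitions", {
  sim <- threeBlockSim(mutation = 0, seed = 13)
  truthPart <- split(names(sim$truth$blockAssignments),
                     sim$truth$blockAssignments)
  blocks <- detectBlocks(sim$genotypes, markerMap(sim$genotypes)$snp,
                         ldConfig())
  expect_length(blocks, 3)
  expect_true(all(vapply(blocks, function(b) length(b$snps) > 1,
                         logical(1))))
  for (tp in truthPart)
    expect_true(any(vapply(blocks, function(b) setequal(b$snps, tp),
                           logical(1))))
})

test_that("blocks partition the input SNPs", {
  sim <- threeBlockSim(mutation = 0.02, seed = 17)
  snps <- markerMap(sim$genotypes)$snp
  blocks <- detectBlocks(sim$genotypes, snps, ldConfig())
  members <- unlist(lapply(blocks, `[[`, "snps"))
  expect_setequal(members, snps)
  expect_equal(length(members), length(snps))
})

test_that("weakly linked SNPs become singletons; the window splits r2 = 1 pairs", {
  set.seed(3)
  d <- matrix(sample(0:2, 50 * 4, replace = TRUE), 50, 4,
              dimnames = list(paste0("s", 1:50), paste0("L", 1:4)))
  g <- toyGenotypes(d, pos = c(1000L, 2000L, 3000L, 4000L))
  blocks <- detectBlocks(g, paste0("L", 1:4), ldConfig())
  expect_length(blocks, 4)
  x <- sample(0:2, 50, replace = TRUE)
  d2 <- cbind(A = x, B = x)
  rownames(d2) <- paste0("s", 1:50)
  g2 <- toyGenotypes(d2, pos = c(1L, 300001L))
  blocks2 <- detectBlocks(g2, c("A", "B"), ldConfig())
  expect_length(blocks2, 2)
})

test_that("the dprime_ci mode also isolates the founder blocks", {
  sim <- threeBlockSim(mutation = 0, seed = 13)
  blocks <- detectBlocks(sim$genotypes, markerMap(sim$genotypes)$snp,
                         ldConfig(blockMethod = "dprime_ci",
                                  bootstrapReps = 30), seed = 2)
  # members of one truth block never split across chromosome-distant groups
  expect_gte(length(blocks), 3)
  ba <- sim$truth$blockAssignments
  purity <- vapply(blocks, function(b)
    length(unique(ba[b$snps])) == 1, logical(1))
  expect_true(all(purity))
})

test_that("tags maximize mean within-block r2 (exhaustive oracle)", {
  sim <- threeBlockSim(mutation = 0.03, seed = 19)
  g <- sim$genotypes
  d <- dosageMatrix(g)
  cfg <- ldConfig()
  blocks <- selectTags(detectBlocks(g, markerMap(g)$snp, cfg), g, cfg)
  for (b in blocks) {
    if (length(b$snps) < 2) {
      expect_identical(b$tag, b$snps)
      next
    }
    r2 <- cor(d[, b$snps])^2
    score <- vapply(seq_along(b$snps), function(i)
      mean(r2[i, -i]), numeric(1))
    best <- score[match(b$tag, b$snps)]
    expect_equal(best, max(score), tolerance = 1e-12)
  }
})

test_that("tag selection is invariant to SNP input order", {
  sim <- threeBlockSim(mutation = 0.02, seed = 23)
  g <- sim$genotypes
  snps <- markerMap(g)$snp
  cfg <- ldConfig()
  t1 <- blocksTable(selectTags(detectBlocks(g, snps, cfg), g, cfg))
  set.seed(4)
  t2 <- blocksTable(selectTags(detectBlocks(g, sample(snps), cfg), g, cfg))
  expect_equal(t1, t2)
})

test_that("every non-tag member is covered by a tag at the block r2 level", {
  sim <- threeBlockSim(mutation = 0, seed = 13)
  g <- sim$genotypes
  d <- dosageMatrix(g)
  cfg <- ldConfig()
  blocks <- selectTags(detectBlocks(g, markerMap(g)$snp, cfg), g, cfg)
  tags <- vapply(blocks, `[[`, character(1), "tag")
  for (b in blocks) for (s in setdiff(b$snps, b$tag)) {
    cover <- max(vapply(tags, function(t)
      cor(d[, s], d[, t])^2, numeric(1)))
    expect_gte(cover, cfg$tagR2)
  }
})

test_that("tag regression explains exactly a noiseless construction", {
  set.seed(5)
  n <- 60
  x1 <- rbinom(n, 2, 0.4)
  x2 <- rbinom(n, 2, 0.3)
  d <- cbind(t1 = x1, t2 = x2)
  rownames(d) <- paste0("s", 1:n)
  g <- toyGenotypes(d, pos = c(1000L, 500000L))
  y <- setNames(5 + 3 * x1, rownames(d))
  val <- suppressWarnings(validateTagsRegression(g, "t1", y))
  expect_equal(val$adjustedR2, 1, tolerance = 1e-12)
  expect_equal(unname(val$coefficients["t1"]), 3, tolerance = 1e-12)
})

test_that("tag regression finds nothing in independent phenotypes", {
  set.seed(6)
  n <- 100
  d <- cbind(t1 = rbinom(n, 2, 0.4), t2 = rbinom(n, 2, 0.3))
  rownames(d) <- paste0("s", 1:n)
  g <- toyGenotypes(d, pos = c(1000L, 2000L))
  y <- setNames(rnorm(n), rownames(d))
  expect_lt(abs(validateTagsRegression(g, c("t1", "t2"), y)$adjustedR2),
            0.1)
})

test_that("tag regression recovers the QTL-explained variance fraction", {
  set.seed(7)
  n <- 1000
  x <- rbinom(n, 2, 0.4)
  target <- 0.6
  sigma <- sqrt(var(x) * (1 - target) / target)
  d <- cbind(qtl = x)
  rownames(d) <- paste0("s", 1:n)
  g <- toyGenotypes(d)
  y <- setNames(x + rnorm(n, 0, sigma), rownames(d))
  trueFrac <- var(x) / var(y)
  expect_lt(abs(validateTagsRegression(g, "qtl", y)$adjustedR2 - trueFrac),
            0.05)
})

test_that("collinear tags are reported and rank-reduced", {
  set.seed(8)
  x <- rbinom(40, 2, 0.5)
  d <- cbind(t1 = x, t2 = x)
  rownames(d) <- paste0("s", 1:40)
  g <- toyGenotypes(d, pos = c(1000L, 2000L))
  y <- setNames(x + rnorm(40, 0, 0.5), rownames(d))
  expect_warning(val <- validateTagsRegression(g, c("t1", "t2"), y),
                 "collinear")
  expect_identical(val$droppedTags, "t2")
})

test_that("per-environment adjusted R2 is reported from long tables", {
  set.seed(9)
  n <- 50
  x <- rbinom(n, 2, 0.4)
  d <- cbind(tag = x)
  rownames(d) <- paste0("s", 1:n)
  g <- toyGenotypes(d)
  long <- expand.grid(accession = rownames(d),
                      environment = c("E1", "E2"), replicate = "R1",
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$trait <- "T"
  long$value <- 2 * x[match(long$accession, rownames(d))] +
    rnorm(nrow(long), 0, 0.4)
  blues <- setNames(tapply(long$value, long$accession, mean)[rownames(d)],
                    rownames(d))
  val <- validateTagsRegression(g, "tag", blues, phenoTable = long,
                                trait = "T")
  expect_length(val$perEnvAdjustedR2, 2)
  expect_true(all(val$perEnvAdjustedR2 > 0.8))
})

test_that("genotype-class comparison matches a hand-computed Welch test", {
  a <- c(10, 12, 14)
  b <- c(20, 21, 25)
  d <- cbind(tag = c(0, 0, 0, 2, 2, 2))
  rownames(d) <- paste0("s", 1:6)
  g <- toyGenotypes(d)
  y <- setNames(c(a, b), rownames(d))
  res <- genotypeClassComparison(g, "tag", y)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  tHand <- (mean(a) - mean(b)) / se
  expect_equal(res$t, tHand, tolerance = 1e-12)
  dfHand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  pHand <- 2 * pt(-abs(tHand), dfHand)
  expect_equal(res$p, pHand, tolerance = 1e-9)
  expect_equal(res$groupStats$n, c(3L, 0L, 3L))
})

test_that("degenerate and underfilled classes are flagged", {
  d <- cbind(tag = c(0, 0, 0, 2, 2, 2, 1))
  rownames(d) <- paste0("s", 1:7)
  g <- toyGenotypes(d)
  y <- setNames(c(2, 2, 2, 8, 8, 8, 5), rownames(d))
  res <- genotypeClassComparison(g, "tag", y)
  expect_true(res$degenerate)
  expect_lte(res$p, .Machine$double.xmin)
  expect_false(res$groupStats$included[res$groupStats$class == 1])
  same <- genotypeClassComparison(g, "tag",
                                  setNames(rep(4, 7), rownames(d)))
  expect_equal(same$p, 1)
})

test_that("the homozygote test is calibrated under the null", {
  set.seed(10)
  d <- cbind(tag = rep(c(0, 2), each = 15))
  rownames(d) <- paste0("s", 1:30)
  g <- toyGenotypes(d)
  ps <- replicate(200, genotypeClassComparison(
    g, "tag", setNames(rnorm(30), rownames(d)))$p)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})
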