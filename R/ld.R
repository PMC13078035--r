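#' LD analysis configuration
#'
#' @param tagR2 minimum pairwise r2 for two SNPs to join a haplotype block
#'   (default 0.8).
#' @param tagWindowBp maximum distance for block membership edges (default
#'   250 kb).
#' @param representativeWindowBp window within which a candidate tag's mean
#'   r2 to its block mates is computed (default 500 kb).
#' @param blockMethod `"r2_cluster"` (default; single-linkage clustering of
#'   r2 >= tagR2 edges) or `"dprime_ci"` (bootstrap confidence-interval
#'   strong-LD rule on D').
#' @param dprimeCiLow,dprimeCiHigh strong-LD bounds for the D' CI rule
#'   (defaults 0.70 and 0.98).
#' @param bootstrapReps bootstrap resamples for the D' CI (default 50).
#' @return list of class `LDConfig`.
#' @export
ldConfig <- function(tagR2 = 0.8, tagWindowBp = 250000,
                     representativeWindowBp = 500000,
                     blockMethod = c("r2_cluster", "dprime_ci"),
                     dprimeCiLow = 0.70, dprimeCiHigh = 0.98,
                     bootstrapReps = 50L) {
  if (tagR2 <= 0 || tagR2 > 1) stop("tagR2 must lie in (0, 1]")
  if (tagWindowBp <= 0 || representativeWindowBp <= 0)
    stop("windows must be positive")
  cfg <- list(tagR2 = tagR2, tagWindowBp = tagWindowBp,
              representativeWindowBp = representativeWindowBp,
              blockMethod = match.arg(blockMethod),
              dprimeCiLow = dprimeCiLow, dprimeCiHigh = dprimeCiHigh,
              bootstrapReps = as.integer(bootstrapReps))
  class(cfg) <- "LDConfig"
  cfg
}

# EM haplotype-frequency estimate for two unphased biallelic loci under HWE;
# returns the frequency of the haplotype carrying the counted allele at both
.emHaplotypeFreq <- function(x, y, tol = 1e-10, maxIter = 200L) {
  n <- length(x)
  pA <- mean(x) / 2
  pB <- mean(y) / 2
  dblHet <- sum(x == 1 & y == 1)
  # haplotypes fully resolved for every other genotype combination
  known <- sum((x == 2) * (y == 2) * 2 + (x == 2) * (y == 1) +
                 (x == 1) * (y == 2))
  p11 <- pA * pB
  for (iter in seq_len(maxIter)) {
    num <- p11 * (1 - pA - pB + p11)
    den <- num + (pA - p11) * (pB - p11)
    w <- if (den > 0) num / den else 0.5
    p11New <- (known + w * dblHet) / (2 * n)
    lo <- max(0, pA + pB - 1)
    hi <- min(pA, pB)
    p11New <- min(max(p11New, lo), hi)
    if (abs(p11New - p11) < tol) {
      p11 <- p11New
      break
    }
    p11 <- p11New
  }
  c(p11 = p11, pA = pA, pB = pB)
}

.dprimeFromFreq <- function(p11, pA, pB) {
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(0)
  abs(D) / dmax
}

.pairDosages <- function(g, i, j) {
  d <- if (is.matrix(g)) g else dosageMatrix(g)
  x <- d[, i]
  y <- d[, j]
  ok <- !is.na(x) & !is.na(y)
  list(x = as.numeric(x[ok]), y = as.numeric(y[ok]))
}

#' Pairwise linkage disequilibrium between two SNPs
#'
#' `r2` is the squared Pearson correlation of the dosage vectors (composite,
#' genotype-level LD -- no phasing required). `dprime` is computed from
#' EM-estimated haplotype frequencies under Hardy-Weinberg equilibrium,
#' normalized by the frequency-bound maximum |D|. The HWE assumption of the
#' EM matters for heavily selfed material; r2 is unaffected.
#'
#' @param g a [GenotypeData-class] or dosage matrix.
#' @param i,j SNP ids or column indices.
#' @return named vector `c(r2, dprime)`.
#' @export
ldPair <- function(g, i, j) {
  p <- .pairDosages(g, i, j)
  if (length(p$x) < 2 || sd(p$x) == 0 || sd(p$y) == 0)
    stop("LD undefined: monomorphic or insufficient paired genotypes")
  r2 <- cor(p$x, p$y)^2
  f <- .emHaplotypeFreq(p$x, p$y)
  c(r2 = unname(r2),
    dprime = unname(.dprimeFromFreq(f[["p11"]], f[["pA"]], f[["pB"]])))
}

# squared-correlation matrix on pairwise-complete dosages
.r2Matrix <- function(d) {
  suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
}

.unionFind <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1])
    b <- find(edges[k, 2])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1))
}

#' Detect haplotype blocks among candidate SNPs
#'
#' Default `r2_cluster` method: an edge joins two candidate SNPs iff they
#' lie on the same chromosome within `tagWindowBp` of each other and their
#' r2 is at least `tagR2`; blocks are the connected components
#' (single-linkage), ordered by chromosome and position. Singleton SNPs form
#' singleton blocks, so the output partitions the input. The `dprime_ci`
#' mode instead requires the bootstrap percentile CI of D' to satisfy the
#' strong-LD bounds (an alternative in the spirit of CI-based block
#' callers); it shares the window rule.
#'
#' @param g a [GenotypeData-class].
#' @param snps SNP ids (e.g. the significant scan hits) to group.
#' @param cfg an [ldConfig()].
#' @param seed RNG seed for the `dprime_ci` bootstrap (default 1).
#' @return list of blocks, each a list with `chrom`, `members` (positions,
#'   sorted), `snps` (ids, position-sorted) and `tag` (NA until
#'   [selectTags()]).
#' @export
detectBlocks <- function(g, snps, cfg = ldConfig(), seed = 1L) {
  stopifnot(inherits(cfg, "LDConfig"))
  map <- markerMap(g)
  idx <- match(snps, map$snp)
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(head(snps[is.na(idx)]), collapse = ", "))
  map <- map[idx, , drop = FALSE]
  d <- dosageMatrix(g)[, snps, drop = FALSE]
  m <- length(snps)
  if (m == 1) {
    blocks <- list(list(chrom = map$chrom, members = map$pos,
                        snps = snps, tag = NA_character_))
    return(blocks)
  }
  r2 <- .r2Matrix(d)
  pairs <- which(upper.tri(r2), arr.ind = TRUE)
  sameChrom <- map$chrom[pairs[, 1]] == map$chrom[pairs[, 2]]
  close <- abs(map$pos[pairs[, 1]] - map$pos[pairs[, 2]]) <= cfg$tagWindowBp
  if (cfg$blockMethod == "r2_cluster") {
    strong <- r2[pairs] >= cfg$tagR2
  } else {
    set.seed(seed)
    strong <- vapply(seq_len(nrow(pairs)), function(k) {
      if (!sameChrom[k] || !close[k]) return(FALSE)
      p <- .pairDosages(d, pairs[k, 1], pairs[k, 2])
      if (sd(p$x) == 0 || sd(p$y) == 0) return(FALSE)
      dp <- vapply(seq_len(cfg$bootstrapReps), function(b) {
        s <- sample.int(length(p$x), replace = TRUE)
        if (sd(p$x[s]) == 0 || sd(p$y[s]) == 0) return(NA_real_)
        f <- .emHaplotypeFreq(p$x[s], p$y[s])
        unname(.dprimeFromFreq(f[["p11"]], f[["pA"]], f[["pB"]]))
      }, numeric(1))
      dp <- dp[!is.na(dp)]
      if (!length(dp)) return(FALSE)
      ci <- quantile(dp, c(0.05, 0.95), names = FALSE)
      ci[1] >= cfg$dprimeCiLow && ci[2] >= cfg$dprimeCiHigh
    }, logical(1))
  }
  keep <- sameChrom & close & strong & !is.na(strong)
  edges <- pairs[keep, , drop = FALSE]
  comp <- .unionFind(m, edges)
  blocks <- lapply(split(seq_len(m), comp), function(ii) {
    o <- ii[order(map$pos[ii])]
    list(chrom = map$chrom[o[1]], members = map$pos[o],
         snps = snps[o], tag = NA_character_)
  })
  ord <- order(vapply(blocks, `[[`, character(1), "chrom"),
               vapply(blocks, function(b) min(b$members), numeric(1)))
  unname(blocks[ord])
}

#' Select one tag SNP per haplotype block
#'
#' Within each block the tag is the member with the highest mean r2 to the
#' other members lying within `representativeWindowBp`; ties are broken
#' toward the smallest position. Singleton blocks tag themselves. The
#' selection is invariant to the input order of SNPs.
#'
#' @param blocks output of [detectBlocks()].
#' @param g the same [GenotypeData-class].
#' @param cfg an [ldConfig()].
#' @return the blocks with `tag` filled in (SNP id).
#' @export
selectTags <- function(blocks, g, cfg = ldConfig()) {
  d <- dosageMatrix(g)
  lapply(blocks, function(b) {
    if (!length(b$snps)) stop("empty block")
    if (length(b$snps) == 1) {
      b$tag <- b$snps
      return(b)
    }
    r2 <- .r2Matrix(d[, b$snps, drop = FALSE])
    score <- vapply(seq_along(b$snps), function(i) {
      within <- abs(b$members - b$members[i]) <= cfg$representativeWindowBp
      within[i] <- FALSE
      if (!any(within)) return(-Inf)
      mean(r2[i, within])
    }, numeric(1))
    # members are position-sorted, so which.max's first hit is the
    # smallest-position tie-break
    b$tag <- b$snps[which.max(score)]
    b
  })
}

#' Flatten a block list to a table
#'
#' @param blocks output of [detectBlocks()] / [selectTags()].
#' @return data.frame (`block`, `chrom`, `n_snps`, `members`, `tag`).
#' @export
blocksTable <- function(blocks) {
  if (!length(blocks))
    return(data.frame(block = integer(), chrom = character(),
                      n_snps = integer(), members = character(),
                      tag = character()))
  data.frame(
    block = seq_along(blocks),
    chrom = vapply(blocks, `[[`, character(1), "chrom"),
    n_snps = vapply(blocks, function(b) length(b$snps), integer(1)),
    members = vapply(blocks, function(b)
      paste(b$members, collapse = ","), character(1)),
    tag = vapply(blocks, function(b)
      if (is.na(b$tag)) NA_character_ else b$tag, character(1)),
    stringsAsFactors = FALSE)
}

#' Validate a tag panel by multiple regression
#'
#' Ordinary least squares of the phenotype on the 0/1/2-encoded tag dosages
#' (0 = major-allele homozygote, 1 = heterozygote, 2 = minor-allele
#' homozygote -- the orientation [GenotypeData()] guarantees). Reports the
#' coefficient vector and adjusted R2 = 1 - (1 - R2)(n - 1)/(n - p - 1),
#' overall on the supplied phenotype (typically BLUEs) and, when a long
#' phenotype table is given, per environment on per-accession means.
#' Collinear tags are reported and the fit is rank-reduced (lm drops them).
#'
#' @param g a [GenotypeData-class].
#' @param tags tag SNP ids.
#' @param blues named phenotype vector or a `computeBLUEs()` data.frame.
#' @param phenoTable optional long-format phenotype table for per-environment
#'   fits.
#' @param trait trait name in `phenoTable`.
#' @return list of class `TagValidationResult`: `coefficients`,
#'   `adjustedR2`, `perEnvAdjustedR2`, `n`, `droppedTags`.
#' @export
validateTagsRegression <- function(g, tags, blues, phenoTable = NULL,
                                   trait = NULL) {
  if (is.data.frame(blues)) blues <- setNames(blues$blue, blues$accession)
  d <- dosageMatrix(g)[, tags, drop = FALSE]
  common <- intersect(names(blues), rownames(d))
  X <- d[common, , drop = FALSE]
  keep <- complete.cases(X)
  common <- common[keep]
  if (length(common) < length(tags) + 2)
    stop("need at least ", length(tags) + 2,
         " samples with phenotype and complete tag genotypes")
  fitOne <- function(y, ids) {
    df <- data.frame(y = y, d[ids, tags, drop = FALSE], check.names = FALSE)
    fit <- lm(y ~ ., data = df)
    list(fit = fit, adjR2 = summary(fit)$adj.r.squared)
  }
  overall <- fitOne(blues[common], common)
  cf <- coef(overall$fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped))
    warning("collinear tag(s) dropped from the fit: ",
            paste(gsub("`", "", dropped), collapse = ", "))
  perEnv <- NULL
  if (!is.null(phenoTable)) {
    stopifnot(!is.null(trait))
    sub <- .phenoSubset(phenoTable, trait)
    means <- aggregate(value ~ accession + environment, data = sub,
                       FUN = mean)
    perEnv <- vapply(split(means, means$environment), function(me) {
      ids <- intersect(me$accession, common)
      if (length(ids) < length(tags) + 2) return(NA_real_)
      fitOne(setNames(me$value[match(ids, me$accession)], ids), ids)$adjR2
    }, numeric(1))
  }
  out <- list(coefficients = cf, adjustedR2 = overall$adjR2,
              perEnvAdjustedR2 = perEnv, n = length(common),
              droppedTags = gsub("`", "", dropped))
  class(out) <- "TagValidationResult"
  out
}

#' Compare phenotypes between genotype classes at a SNP
#'
#' Per dosage class (0/1/2) sample size, mean and SD, plus a Welch two-sided
#' t-test between the two homozygote classes (heterozygotes are reported but
#' not tested). Classes with fewer than 2 samples are excluded and flagged;
#' zero-variance comparisons are flagged degenerate with p at the machine
#' floor (different means) or 1 (equal means).
#'
#' @param g a [GenotypeData-class].
#' @param tag SNP id.
#' @param phenotype named phenotype vector.
#' @return list: `groupStats` data.frame (`class`, `n`, `mean`, `sd`,
#'   `included`), `t`, `p`, `degenerate`.
#' @export
genotypeClassComparison <- function(g, tag, phenotype) {
  d <- dosageMatrix(g)[, tag]
  common <- intersect(names(phenotype), names(d))
  d <- d[common]
  y <- phenotype[common]
  ok <- !is.na(d) & !is.na(y)
  d <- d[ok]
  y <- y[ok]
  stats <- do.call(rbind, lapply(0:2, function(cl) {
    v <- y[d == cl]
    data.frame(class = cl, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               included = length(v) >= 2)
  }))
  a <- y[d == 0]
  b <- y[d == 2]
  t <- p <- NA_real_
  degenerate <- FALSE
  if (length(a) >= 2 && length(b) >= 2) {
    if (sd(a) == 0 && sd(b) == 0) {
      degenerate <- TRUE
      p <- if (mean(a) == mean(b)) 1 else .Machine$double.xmin
      t <- if (mean(a) == mean(b)) 0 else Inf
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
      t <- unname(tt$statistic)
      p <- tt$p.value
    }
  }
  list(groupStats = stats, t = t, p = p, degenerate = degenerate)
}
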