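#' Build the VanRaden genomic relationship matrix
#'
#' `Z` is the dosage matrix column-centred by twice the allele frequency
#' (`M - 2p`, frequencies from the full panel supplied -- reference and
#' candidates together), and `G = ZZ' / (2 * sum(p_i (1 - p_i)))`. An
#' optional ridge `blendEpsilon * I` is added for invertibility and recorded
#' in the object.
#'
#' @param g a [GenotypeData-class] or complete samples x SNPs dosage matrix
#'   (missing dosages are mean-imputed first).
#' @param blendEpsilon diagonal blend (default 1e-6; use 0 for the raw
#'   matrix).
#' @return a [GRM-class].
#' @examples
#' m <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' grmMatrix(buildGRM(m, blendEpsilon = 0))  # [[2, -2], [-2, 2]]
#' @export
buildGRM <- function(g, blendEpsilon = 1e-6) {
  M <- meanImpute(g)
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs monomorphic (zero VanRaden denominator); need ",
         "polymorphic markers")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  if (blendEpsilon > 0) G <- G + diag(blendEpsilon, nrow(G))
  dimnames(G) <- list(rownames(M), rownames(M))
  methods::new("GRM", matrix = G, sampleIds = rownames(M),
               denominator = denom, blendEpsilon = blendEpsilon)
}

# Henderson MME for the GBLUP model at a fixed variance ratio k:
# X (nP x q) fixed design, Z (nP x N) incidence into all accessions.
.solveMME <- function(G, y, phenoIdx, k) {
  N <- nrow(G)
  nP <- length(phenoIdx)
  X <- matrix(1, nP, 1)
  Z <- matrix(0, nP, N)
  Z[cbind(seq_len(nP), phenoIdx)] <- 1
  Ginv <- tryCatch(solve(G), error = function(e)
    stop("GRM is not invertible (condition number ",
         format(kappa(G), digits = 3), "); increase blendEpsilon"))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + Ginv * k))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("mixed-model equations are singular (condition number ",
         format(kappa(C), digits = 3), ")"))
  list(b = unname(sol[1]), u = unname(sol[-1]))
}

#' Fit the GBLUP model
#'
#' Estimates the additive and residual variances by spectral REML
#' ([fitNullVarianceRatio()]) on the phenotyped submatrix of the GRM, then
#' solves Henderson's mixed-model equations with `k = sigma2e/sigma2a` over
#' *all* accessions in the GRM (joint G), so the returned breeding values
#' cover candidates without phenotypes.
#'
#' @param grm a [GRM-class] covering reference and candidate accessions.
#' @param blues named phenotype vector or a [computeBLUEs()] data.frame;
#'   accessions absent from it are treated as unphenotyped candidates.
#' @param phenotypedIds optional explicit subset of accessions whose
#'   phenotypes enter the fit (the training set).
#' @param fixedK optional fixed variance ratio; skips the REML step (used by
#'   cross-validation when per-fold refitting is switched off, and by the
#'   small-system oracle tests).
#' @return a [GBLUPFit-class].
#' @export
fitGBLUP <- function(grm, blues, phenotypedIds = NULL, fixedK = NULL) {
  stopifnot(methods::is(grm, "GRM"))
  if (is.data.frame(blues)) blues <- setNames(blues$blue, blues$accession)
  ids <- sampleIds(grm)
  pheno <- intersect(if (is.null(phenotypedIds)) names(blues)
                     else phenotypedIds, ids)
  pheno <- pheno[!is.na(blues[pheno])]
  if (length(pheno) < 3) stop("fewer than 3 phenotyped accessions")
  if (length(pheno) < 30)
    warning("only ", length(pheno), " phenotyped accessions; variance ",
            "components will be poorly resolved")
  G <- grmMatrix(grm)
  y <- blues[pheno]
  boundary <- FALSE
  if (is.null(fixedK)) {
    null <- withCallingHandlers(
      fitNullVarianceRatio(y, G[pheno, pheno]),
      warning = function(w) invokeRestart("muffleWarning"))
    sigma2a <- null$sigma2g
    sigma2e <- null$sigma2e
    boundary <- null$degenerate || null$delta <= 1.1e-5 ||
      null$delta >= 0.9e5
    k <- null$delta
  } else {
    k <- fixedK
    sigma2a <- NA_real_
    sigma2e <- NA_real_
  }
  sol <- .solveMME(G, y, match(pheno, ids), k)
  h2 <- if (is.null(fixedK)) sigma2a / (sigma2a + sigma2e) else 1 / (1 + k)
  methods::new("GBLUPFit",
               sigma2a = if (is.null(fixedK)) sigma2a else h2,
               sigma2e = if (is.null(fixedK)) sigma2e else h2 * k,
               k = k, h2Narrow = h2,
               fixedEffects = sol$b,
               gebv = setNames(sol$u, ids),
               phenotyped = setNames(ids %in% pheno, ids),
               boundary = boundary,
               blendEpsilon = grm@blendEpsilon)
}

#' Narrow-sense heritability from additive and residual variances
#'
#' `h2 = sigma2a / (sigma2a + sigma2e)` -- the single-trial genomic
#' heritability the GBLUP variance components imply.
#'
#' @param sigma2a additive genetic variance.
#' @param sigma2e residual variance.
#' @return heritability in \[0, 1\].
#' @examples
#' narrowSenseH2(0.8626, 1.6915)  # 0.3377
#' @export
narrowSenseH2 <- function(sigma2a, sigma2e) {
  if (sigma2a < 0 || sigma2e < 0) stop("variances must be non-negative")
  if (sigma2a + sigma2e <= 0) stop("heritability undefined: zero variance")
  sigma2a / (sigma2a + sigma2e)
}

#' Cross-validated predictive ability and accuracy
#'
#' Repeated k-fold cross-validation of the GBLUP model: per repeat a seeded
#' random disjoint fold assignment; per fold the model is refit on the
#' training portion (variance components re-estimated unless
#' `refitVariance = FALSE`, which reuses the full-data ratio) and held-out
#' GEBVs are predicted through the joint MME. Predictive ability is the mean
#' Pearson r(GEBV, phenotype) over the folds x repeats fits; accuracy is
#' predictive ability divided by the square root of the full-data
#' heritability. Folds that would hold out fewer than 3 accessions are
#' merged into a neighbour with a warning.
#'
#' @param grm a [GRM-class].
#' @param blues named phenotype vector or [computeBLUEs()] data.frame.
#' @param folds number of folds (default 5).
#' @param repeats number of repeats (default 20; 5 x 20 = 100 fits).
#' @param seed RNG seed for the fold assignments.
#' @param refitVariance refit variance components per fold (default TRUE).
#' @return list of class `CVMetrics`: `predictiveAbility`, `accuracy`,
#'   `h2Narrow`, `perFold` data.frame, `folds`, `repeats`, `seed`.
#' @export
crossValidate <- function(grm, blues, folds = 5L, repeats = 20L, seed = 1L,
                          refitVariance = TRUE) {
  if (is.data.frame(blues)) blues <- setNames(blues$blue, blues$accession)
  ids <- intersect(names(blues)[!is.na(blues)], sampleIds(grm))
  nP <- length(ids)
  if (nP < folds) stop("fewer phenotyped accessions than folds")
  fullFit <- suppressWarnings(fitGBLUP(grm, blues, phenotypedIds = ids))
  h2 <- narrowH2(fullFit)
  set.seed(seed)
  rows <- list()
  for (r in seq_len(repeats)) {
    lab <- sample(rep_len(seq_len(folds), nP))
    tab <- tabulate(lab, folds)
    while (any(tab > 0 & tab < 3) && sum(tab > 0) > 1) {
      small <- which.min(ifelse(tab > 0, tab, Inf))
      others <- setdiff(which(tab > 0), small)
      target <- others[which.min(tab[others])]
      lab[lab == small] <- target
      warning("fold with fewer than 3 test samples merged into a neighbour")
      tab <- tabulate(lab, folds)
    }
    if (sum(tab > 0) < 2)
      stop("too few phenotyped accessions for ", folds, "-fold ",
           "cross-validation")
    for (f in sort(unique(lab))) {
      test <- ids[lab == f]
      train <- setdiff(ids, test)
      fit <- suppressWarnings(fitGBLUP(
        grm, blues, phenotypedIds = train,
        fixedK = if (refitVariance) NULL else fullFit@k))
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, nTest = length(test),
        r = suppressWarnings(cor(gebv(fit)[test], blues[test])))
    }
  }
  perFold <- do.call(rbind, rows)
  pa <- mean(perFold$r, na.rm = TRUE)
  out <- list(predictiveAbility = pa,
              accuracy = pa / sqrt(h2),
              h2Narrow = h2, perFold = perFold,
              folds = as.integer(folds), repeats = as.integer(repeats),
              seed = as.integer(seed))
  class(out) <- "CVMetrics"
  out
}

#' Elite-retention under GEBV-based culling
#'
#' Designates the top-`m` candidates by phenotype as the elite set, then for
#' each reduction fraction `f` removes the `floor(f * N)` candidates with
#' the lowest GEBV and reports how many elites survive. Ties in either
#' ranking are broken by accession id (ascending), so the analysis is
#' deterministic.
#'
#' @param gebvValues named GEBV vector over the N candidates.
#' @param phenotype named phenotype vector over the same candidates.
#' @param m elite-set size (default 12).
#' @param fractions reduction fractions (default c(0.2, 0.3, 0.4, 0.5)).
#' @return data.frame of class `RetentionCurve` (`fraction`, `removed`,
#'   `candidates_kept`, `elites_retained`, `retention_rate`), with the elite
#'   ids in attribute `elite`.
#' @export
retentionAnalysis <- function(gebvValues, phenotype, m = 12L,
                              fractions = c(0.2, 0.3, 0.4, 0.5)) {
  ids <- intersect(names(gebvValues), names(phenotype))
  N <- length(ids)
  if (N < 2) stop("need at least 2 candidates with both GEBV and phenotype")
  if (m >= N) stop("elite-set size m must be smaller than the number of ",
                   "candidates (m = ", m, ", N = ", N, ")")
  ge <- gebvValues[ids]
  ph <- phenotype[ids]
  elite <- ids[order(-ph, ids)][seq_len(m)]
  cullOrder <- ids[order(ge, ids)]
  rows <- lapply(fractions, function(f) {
    nRemove <- floor(f * N)
    survivors <- setdiff(ids, cullOrder[seq_len(nRemove)])
    kept <- sum(elite %in% survivors)
    data.frame(fraction = f, removed = nRemove,
               candidates_kept = N - nRemove, elites_retained = kept,
               retention_rate = kept / m)
  })
  out <- do.call(rbind, rows)
  attr(out, "elite") <- elite
  attr(out, "m") <- m
  attr(out, "N") <- N
  class(out) <- c("RetentionCurve", "data.frame")
  out
}

#' Pearson correlation between GEBVs and phenotypes
#'
#' @param gebvValues,phenotype named vectors over shared candidates.
#' @return list: `r`, `p` (two-sided, t-based), `n`.
#' @export
gebvPhenotypeCorrelation <- function(gebvValues, phenotype) {
  ids <- intersect(names(gebvValues), names(phenotype))
  if (length(ids) < 3) stop("need at least 3 candidates")
  if (sd(gebvValues[ids]) == 0 || sd(phenotype[ids]) == 0)
    stop("correlation undefined: zero variance")
  ct <- cor.test(gebvValues[ids], phenotype[ids], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids))
}
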