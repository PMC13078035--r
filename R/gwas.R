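#' REML estimate of the residual/genetic variance ratio under a kinship model
#'
#' Fits `y = Xb + u + e` with `u ~ N(0, sigma2g * K)` by spectral
#' decomposition: the restricted likelihood is profiled down to a 1-D
#' function of `delta = sigma2e/sigma2g`, maximized on a log grid refined by
#' `optimize()`. The eigendecomposition of K is cached for reuse by the
#' per-SNP scan.
#'
#' When K is (numerically) proportional to the identity the ratio is
#' unidentifiable -- the restricted likelihood is flat in `delta`; a warning
#' is raised and `delta` is returned at the lower search bound with
#' `degenerate = TRUE`.
#'
#' @param y named numeric phenotype vector (typically BLUEs).
#' @param K kinship/GRM matrix matching `y` (a [GRM-class] is accepted).
#' @param X fixed-effect design matrix (default: intercept only).
#' @param deltaRange log10 search bounds for delta (default c(-5, 5)).
#' @return list: `delta`, `sigma2g`, `sigma2e`, `logLik`, `degenerate`,
#'   `reml` (the profiled restricted log-likelihood as a function of delta),
#'   and the cached `eigenValues`/`eigenVectors` of K.
#' @export
fitNullVarianceRatio <- function(y, K, X = NULL, deltaRange = c(-5, 5)) {
  if (methods::is(K, "GRM")) K <- grmMatrix(K)
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    common <- intersect(names(y), rownames(K))
    if (length(common) < 2) stop("y and K share fewer than 2 samples")
    y <- y[common]
    K <- K[common, common]
  }
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)

  eigK <- eigen(K, symmetric = TRUE)
  if (min(eigK$values) < -1e-6 * max(abs(eigK$values)))
    stop("K is not positive semi-definite; blend the GRM ",
         "(buildGRM(..., blendEpsilon > 0)) before fitting")

  P <- diag(n) - X %*% solve(crossprod(X), t(X))
  eigS <- eigen(P %*% K %*% P, symmetric = TRUE)
  xi <- eigS$values[seq_len(n - q)]
  xi <- pmax(xi, 0)
  eta <- as.numeric(crossprod(eigS$vectors[, seq_len(n - q), drop = FALSE],
                              y))
  m <- n - q
  reml <- function(delta) {
    w <- xi + delta
    0.5 * (m * (log(m / (2 * pi)) - 1 - log(sum(eta^2 / w))) -
             sum(log(w)))
  }
  grid <- 10^seq(deltaRange[1], deltaRange[2], length.out = 120)
  ll <- vapply(grid, reml, numeric(1))
  degenerate <- FALSE
  if (diff(range(ll)) < 1e-6) {
    warning("variance ratio is unidentifiable (K is proportional to the ",
            "identity); returning delta at the search boundary")
    delta <- grid[1]
    degenerate <- TRUE
  } else {
    i <- which.max(ll)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    opt <- optimize(function(ld) reml(10^ld), interval = log10(c(lo, hi)),
                    maximum = TRUE, tol = 1e-8)
    delta <- 10^opt$maximum
    if (reml(grid[i]) > reml(delta)) delta <- grid[i]
  }
  sigma2g <- sum(eta^2 / (xi + delta)) / m
  list(delta = delta, sigma2g = sigma2g, sigma2e = delta * sigma2g,
       logLik = reml(delta), degenerate = degenerate, reml = reml,
       eigenValues = eigK$values, eigenVectors = eigK$vectors,
       sampleIds = if (!is.null(names(y))) names(y) else NULL)
}

#' Mixed-linear-model association scan
#'
#' Per-SNP generalized least squares of the phenotype on (intercept,
#' dosage) with covariance `sigma2g (K + delta I)`; `delta` is estimated
#' once on the null model and reused for every SNP (the standard one-ratio
#' approximation). Each test is a 1-df Wald chi-square. The per-SNP
#' proportion of variance explained (PVE) is the squared partial correlation
#' of the dosage with the phenotype in the kinship-whitened space, and the
#' per-SNP analytic power is evaluated at that PVE (see [analyticPower()]).
#'
#' Monomorphic (zero-variance) SNPs are flagged `tested = FALSE` and not
#' tested.
#'
#' @param g a [GenotypeData-class] or complete samples x SNPs dosage matrix
#'   (missing dosages are mean-imputed).
#' @param y named phenotype vector (BLUEs).
#' @param K kinship matrix or [GRM-class]; `NULL` fits an identity (no
#'   correction, ordinary least squares).
#' @param null optional precomputed [fitNullVarianceRatio()] result.
#' @param powerAlpha significance level used for the per-SNP power column
#'   (default 1e-7, the program's fixed genome-wide threshold).
#' @return data.frame of class `AssocResult`: one row per SNP with `snp`,
#'   `chrom`, `pos`, `maf`, `beta`, `se`, `stat`, `p`, `neglog10p`, `pve`,
#'   `power`, `tested`.
#' @export
scanAssociation <- function(g, y, K = NULL, null = NULL, powerAlpha = 1e-7) {
  if (methods::is(K, "GRM")) K <- grmMatrix(K)
  M <- meanImpute(g)
  map <- if (methods::is(g, "GenotypeData")) markerMap(g) else
    data.frame(snp = colnames(M), chrom = NA_character_, pos = NA_integer_,
               maf = colMeans(M) / 2, stringsAsFactors = FALSE)
  common <- intersect(names(y), rownames(M))
  if (length(common) < 3) stop("fewer than 3 samples shared by y and g")
  y <- y[common]
  M <- M[common, , drop = FALSE]
  n <- length(y)
  if (is.null(K)) K <- diag(n)
  else if (!is.null(rownames(K))) K <- K[common, common]
  stopifnot(nrow(K) == n, ncol(K) == n)

  if (is.null(null))
    null <- suppressWarnings(fitNullVarianceRatio(y, K))
  delta <- null$delta
  ev <- if (!is.null(null$sampleIds) &&
            identical(null$sampleIds, common)) {
    list(values = null$eigenValues, vectors = null$eigenVectors)
  } else {
    e <- eigen(K, symmetric = TRUE)
    list(values = e$values, vectors = e$vectors)
  }
  w <- ev$values + delta
  if (min(w) <= 0) stop("K + delta*I is singular; blend the GRM")
  W <- ev$vectors %*% (t(ev$vectors) / sqrt(w))

  ty <- as.numeric(W %*% y)
  t1 <- as.numeric(W %*% rep(1, n))
  TG <- W %*% M
  # residualize on the whitened intercept
  s11 <- sum(t1^2)
  ry <- ty - t1 * sum(t1 * ty) / s11
  RG <- TG - t1 %*% (crossprod(t1, TG) / s11)
  Sxx <- colSums(RG^2)
  Sxy <- as.numeric(crossprod(RG, ry))
  Syy <- sum(ry^2)

  rawVar <- apply(M, 2, var)
  tested <- rawVar > 1e-12 & Sxx > 1e-12 * max(Sxx, 1)
  beta <- se <- stat <- p <- pve <- rep(NA_real_, ncol(M))
  i <- tested
  beta[i] <- Sxy[i] / Sxx[i]
  rss <- Syy - beta[i] * Sxy[i]
  sigma2 <- rss / (n - 2)
  se[i] <- sqrt(sigma2 / Sxx[i])
  stat[i] <- (beta[i] / se[i])^2
  p[i] <- pchisq(stat[i], df = 1, lower.tail = FALSE)
  pve[i] <- Sxy[i]^2 / (Sxx[i] * Syy)
  power <- rep(NA_real_, ncol(M))
  power[i] <- analyticPower(n = n, r2 = pmin(pve[i], 1 - 1e-12),
                            alpha = powerAlpha)
  out <- data.frame(
    snp = colnames(M),
    chrom = map$chrom[match(colnames(M), map$snp)],
    pos = map$pos[match(colnames(M), map$snp)],
    maf = map$maf[match(colnames(M), map$snp)],
    beta = beta, se = se, stat = stat, p = p,
    neglog10p = -log10(p), pve = pve, power = power, tested = tested,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("AssocResult", "data.frame")
  attr(out, "delta") <- delta
  attr(out, "n") <- n
  out
}

#' Genome-wide significance threshold
#'
#' Bonferroni mode returns `alpha / nSnps`; fixed mode returns the supplied
#' rounded genome-wide cutoff (default 1e-7, i.e. -log10 p = 7) regardless
#' of the SNP count.
#'
#' @param nSnps number of tested SNPs.
#' @param alpha family-wise error rate (default 0.05).
#' @param mode `"bonferroni"` or `"fixed"`.
#' @param fixedP the fixed threshold used when `mode = "fixed"`.
#' @return list: `p` (threshold), `neglog10` and the inputs.
#' @examples
#' bonferroniThreshold(608809)$neglog10  # 7.0855, commonly rounded to 7
#' @export
bonferroniThreshold <- function(nSnps, alpha = 0.05,
                                mode = c("bonferroni", "fixed"),
                                fixedP = 1e-7) {
  mode <- match.arg(mode)
  stopifnot(nSnps >= 1)
  p <- if (mode == "bonferroni") alpha / nSnps else fixedP
  list(p = p, neglog10 = -log10(p), mode = mode, nSnps = nSnps,
       alpha = alpha)
}

#' Noncentrality parameter of the association test
#'
#' `NCP = n * R^2 / (1 - R^2)` for a SNP explaining a fraction `r2` of the
#' phenotypic variance in a sample of size `n`.
#'
#' @param n sample size (>= 2).
#' @param r2 proportion of variance explained, in \[0, 1).
#' @return the noncentrality parameter (vectorized over `r2`).
#' @examples
#' ncpValue(100, 0.5)  # 100
#' @export
ncpValue <- function(n, r2) {
  if (any(n < 2)) stop("n must be at least 2")
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  n * r2 / (1 - r2)
}

#' Analytic power of the association test
#'
#' Upper-tail probability of a noncentral chi-square (df, NCP) beyond the
#' central chi-square (1 - alpha) quantile, with NCP from [ncpValue()]. At
#' `r2 = 0` the power equals `alpha`.
#'
#' @param n sample size.
#' @param r2 proportion of variance explained (vectorized).
#' @param alpha significance level in (0, 1) (default 1e-7).
#' @param df test degrees of freedom (default 1, the single-SNP additive
#'   test).
#' @return power in \[0, 1\].
#' @examples
#' analyticPower(n = 149, r2 = 0.2623)  # ~0.97
#' @export
analyticPower <- function(n, r2, alpha = 1e-7, df = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  q <- qchisq(1 - alpha, df = df)
  pchisq(q, df = df, ncp = ncpValue(n, r2), lower.tail = FALSE)
}

#' Mean analytic power over a panel of significant SNPs
#'
#' @param r2 vector of per-SNP PVE fractions.
#' @inheritParams analyticPower
#' @return mean power over the panel.
#' @export
meanPanelPower <- function(r2, n, alpha = 1e-7, df = 1) {
  mean(analyticPower(n = n, r2 = r2, alpha = alpha, df = df))
}

#' Expected-versus-observed quantile table for a scan
#'
#' Expected quantiles are `-log10((i - 0.5)/m)` for the m tested SNPs,
#' paired against the sorted observed `-log10 p`.
#'
#' @param scan an `AssocResult` from [scanAssociation()].
#' @return data.frame (`expected`, `observed`), one row per tested SNP.
#' @export
qqTable <- function(scan) {
  p <- scan$p[scan$tested]
  m <- length(p)
  if (!m) return(data.frame(expected = numeric(), observed = numeric()))
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = sort(-log10(p), decreasing = TRUE))
}

#' Plot-ready Manhattan table
#'
#' Adds a genome-cumulative coordinate to the tested rows of a scan.
#'
#' @param scan an `AssocResult` from [scanAssociation()].
#' @return data.frame (`snp`, `chrom`, `pos`, `cumPos`, `neglog10p`).
#' @export
manhattanTable <- function(scan) {
  s <- scan[scan$tested, c("snp", "chrom", "pos", "neglog10p")]
  s <- s[order(s$chrom, s$pos), ]
  offsets <- c(0, cumsum(tapply(s$pos, factor(s$chrom,
                                              levels = unique(s$chrom)),
                                max)))
  s$cumPos <- s$pos + offsets[match(s$chrom, unique(s$chrom))]
  rownames(s) <- NULL
  s[, c("snp", "chrom", "pos", "cumPos", "neglog10p")]
}
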