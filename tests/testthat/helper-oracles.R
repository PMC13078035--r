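# Independent oracles shared across test files.

# Brute-force D' oracle: maximize the HWE genotype likelihood over the
# single free haplotype frequency p11 on a fine grid.
bruteForceDprime <- function(x, y) {
  pA <- mean(x) / 2
  pB <- mean(y) / 2
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = 20001)
  logLik <- vapply(grid, function(p11) {
    hap <- c(p11, pA - p11, pB - p11, 1 - pA - pB + p11)
    if (any(hap < -1e-12)) return(-Inf)
    hap <- pmax(hap, 1e-12)
    gp <- matrix(0, 3, 3)  # P(x dosage, y dosage) under HWE
    gp[3, 3] <- hap[1]^2
    gp[3, 2] <- 2 * hap[1] * hap[2]
    gp[3, 1] <- hap[2]^2
    gp[2, 3] <- 2 * hap[1] * hap[3]
    gp[2, 2] <- 2 * (hap[1] * hap[4] + hap[2] * hap[3])
    gp[2, 1] <- 2 * hap[2] * hap[4]
    gp[1, 3] <- hap[3]^2
    gp[1, 2] <- 2 * hap[3] * hap[4]
    gp[1, 1] <- hap[4]^2
    sum(log(pmax(gp[cbind(x + 1, y + 1)], 1e-300)))
  }, numeric(1))
  p11 <- grid[which.max(logLik)]
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) 0 else abs(D) / dmax
}

# dense closed-form BLUP oracle for an intercept-only model:
# b = (1'V^-1 1)^-1 1'V^-1 y with V = G_pp + kI; u = G[, pheno] V^-1 (y - b)
denseBlupOracle <- function(G, y, phenoIds, k) {
  Gpp <- G[phenoIds, phenoIds]
  V <- Gpp + diag(k, length(phenoIds))
  Vi <- solve(V)
  one <- rep(1, length(phenoIds))
  b <- as.numeric(crossprod(one, Vi %*% y[phenoIds]) /
                    crossprod(one, Vi %*% one))
  u <- as.numeric(G[, phenoIds] %*% (Vi %*% (y[phenoIds] - b)))
  list(b = b, u = setNames(u, rownames(G)))
}
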