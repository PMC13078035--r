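.phenoSubset <- function(pheno, trait, environments = NULL) {
  stopifnot(all(c("accession", "environment", "replicate", "trait",
                  "value") %in% names(pheno)))
  sub <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (!is.null(environments))
    sub <- sub[sub$environment %in% environments, , drop = FALSE]
  if (!nrow(sub)) stop("no observations for trait ", trait)
  sub$accession <- factor(sub$accession)
  sub$environment <- factor(sub$environment)
  sub$replicate <- factor(sub$replicate)
  sub
}

#' REML variance components of the multi-environment model
#'
#' Fits (through `lme4::lmer`) the mixed model with environments and
#' replicates nested within environments as fixed effects, and genotypes and
#' genotype-by-environment interactions as random effects:
#' `value ~ environment + environment:replicate + (1|accession) +
#' (1|accession:environment)`. Components at the zero boundary are returned
#' as 0 and flagged.
#'
#' @param pheno long-format phenotype table (accession, environment,
#'   replicate, trait, value).
#' @param trait trait name to model.
#' @param environments optional subset of environments to include (e.g. the
#'   uncontaminated trials for a yield trait).
#' @return list of class `VarianceComponents`: `sigma2g`, `sigma2ge`,
#'   `sigma2eps`, `nEnv`, `nRep`, `boundary`, `trait`.
#' @export
fitMultiEnvModel <- function(pheno, trait, environments = NULL) {
  sub <- .phenoSubset(pheno, trait, environments)
  if (nlevels(sub$environment) < 2)
    stop("need at least 2 environments for variance-component estimation")
  if (nlevels(sub$replicate) < 2) stop("need at least 2 replicates")
  if (nlevels(sub$accession) < 2) stop("need at least 2 genotypes")
  obsPerAcc <- table(sub$accession)
  if (any(obsPerAcc == 0))
    stop("genotype absent from all environments: ",
         paste(names(obsPerAcc)[obsPerAcc == 0], collapse = ", "))
  fit <- suppressMessages(suppressWarnings(lme4::lmer(
    value ~ environment + environment:replicate +
      (1 | accession) + (1 | accession:environment),
    data = sub, REML = TRUE,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- setNames(vc$vcov, vc$grp)
  s2g <- unname(comp["accession"])
  s2ge <- unname(comp["accession:environment"])
  s2e <- unname(comp["Residual"])
  tol <- 1e-8 * max(comp, 1e-12)
  boundary <- c(sigma2g = s2g < tol, sigma2ge = s2ge < tol,
                sigma2eps = s2e < tol)
  out <- list(sigma2g = max(s2g, 0), sigma2ge = max(s2ge, 0),
              sigma2eps = max(s2e, 0),
              nEnv = nlevels(sub$environment),
              nRep = nlevels(sub$replicate),
              boundary = boundary, trait = trait)
  class(out) <- "VarianceComponents"
  out
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \eqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/n + \sigma^2_e/(nr))}
#' with n environments and r replicates per environment.
#'
#' @param v a `VarianceComponents` list ([fitMultiEnvModel()]) or a list
#'   with fields `sigma2g`, `sigma2ge`, `sigma2eps`, `nEnv`, `nRep`.
#' @return heritability in \[0, 1\].
#' @examples
#' broadSenseH2(list(sigma2g = 1, sigma2ge = 2, sigma2eps = 6,
#'                   nEnv = 2, nRep = 3))  # 1/3
#' @export
broadSenseH2 <- function(v) {
  stopifnot(all(c("sigma2g", "sigma2ge", "sigma2eps", "nEnv", "nRep")
                %in% names(v)))
  if (any(c(v$sigma2g, v$sigma2ge, v$sigma2eps) < 0))
    stop("variance components must be non-negative")
  denom <- v$sigma2g + v$sigma2ge / v$nEnv + v$sigma2eps / (v$nEnv * v$nRep)
  if (denom <= 0)
    stop("heritability undefined: all variance components are zero")
  v$sigma2g / denom
}

#' Best linear unbiased estimates per genotype
#'
#' Single fixed-effect least-squares fit of `value ~ accession (+
#' environment + environment:replicate)` (terms included only when they
#' vary); the BLUE of an accession is its fitted value averaged over every
#' environment-replicate cell, so on balanced data it equals the genotype
#' mean. Rank-deficient designs (confounded accession effects) are an
#' error.
#'
#' @inheritParams fitMultiEnvModel
#' @return data.frame (`accession`, `trait`, `blue`) with fitted environment
#'   and replicate effects in attributes `envEffects`/`repEffects`.
#' @export
computeBLUEs <- function(pheno, trait, environments = NULL) {
  sub <- .phenoSubset(pheno, trait, environments)
  terms <- "0 + accession"
  if (nlevels(sub$environment) >= 2) terms <- c(terms, "environment")
  if (nlevels(sub$replicate) >= 2 && nlevels(sub$environment) >= 1)
    terms <- c(terms, "environment:replicate")
  form <- as.formula(paste("value ~", paste(terms, collapse = " + ")))
  fit <- lm(form, data = sub)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; confounded term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  grid <- expand.grid(accession = levels(sub$accession),
                      environment = levels(sub$environment),
                      replicate = levels(sub$replicate),
                      KEEP.OUT.ATTRS = FALSE)
  pred <- predict(fit, newdata = grid)
  blue <- tapply(pred, grid$accession, mean)
  out <- data.frame(accession = names(blue), trait = trait,
                    blue = as.numeric(blue), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "envEffects") <- cf[grep("^environment", names(cf))]
  out
}

#' Per-environment descriptive trait summary
#'
#' Computes max, min, mean, variance, SD and CV(%) of the per-accession
#' means (averaged over replicates) within each environment, plus the
#' across-environment broad-sense heritability when the design allows it.
#'
#' @inheritParams fitMultiEnvModel
#' @return data.frame (`environment`, `max`, `min`, `mean`, `variance`,
#'   `sd`, `cv`).
#' @export
traitSummary <- function(pheno, trait, environments = NULL) {
  sub <- .phenoSubset(pheno, trait, environments)
  means <- aggregate(value ~ accession + environment, data = sub, FUN = mean)
  rows <- lapply(split(means$value, means$environment), function(v) {
    data.frame(max = max(v), min = min(v), mean = mean(v),
               variance = var(v), sd = sd(v),
               cv = if (mean(v) != 0) 100 * sd(v) / mean(v) else 0)
  })
  out <- cbind(environment = names(rows), do.call(rbind, rows))
  rownames(out) <- NULL
  out$variance[is.na(out$variance)] <- 0
  out$sd[is.na(out$sd)] <- 0
  out
}

#' Combined fixed-effects ANOVA across environments
#'
#' `value ~ environment + environment:replicate + accession +
#' environment:accession`, F tests against the residual.
#'
#' @inheritParams fitMultiEnvModel
#' @return data.frame (`term`, `df`, `ss`, `ms`, `f`, `p`).
#' @export
anovaTable <- function(pheno, trait, environments = NULL) {
  sub <- .phenoSubset(pheno, trait, environments)
  fit <- aov(value ~ environment + environment:replicate + accession +
               environment:accession, data = sub)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  rename <- c("environment" = "Environment",
              "environment:replicate" = "Rep(Env)",
              "accession" = "Genotype",
              "environment:accession" = "GxE",
              "Residuals" = "Residual")
  data.frame(term = unname(ifelse(terms %in% names(rename),
                                  rename[terms], terms)),
             df = tab[["Df"]], ss = tab[["Sum Sq"]], ms = tab[["Mean Sq"]],
             f = tab[["F value"]], p = tab[["Pr(>F)"]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-environment Pearson correlation between two traits
#'
#' Correlates per-accession means of the two traits within each shared
#' environment; two-sided p-values via the t transform of r.
#'
#' @param pheno long-format phenotype table.
#' @param trait1,trait2 trait names.
#' @param environments optional environment subset.
#' @return data.frame (`environment`, `n`, `r`, `p`).
#' @export
traitCorrelation <- function(pheno, trait1, trait2, environments = NULL) {
  s1 <- .phenoSubset(pheno, trait1, environments)
  s2 <- .phenoSubset(pheno, trait2, environments)
  m1 <- aggregate(value ~ accession + environment, data = s1, FUN = mean)
  m2 <- aggregate(value ~ accession + environment, data = s2, FUN = mean)
  envs <- intersect(unique(m1$environment), unique(m2$environment))
  rows <- lapply(envs, function(e) {
    a <- m1[m1$environment == e, ]
    b <- m2[m2$environment == e, ]
    j <- merge(a, b, by = "accession")
    if (nrow(j) < 3)
      stop("need at least 3 shared accessions in environment ", e)
    if (sd(j$value.x) == 0 || sd(j$value.y) == 0)
      stop("correlation undefined: zero variance in environment ", e)
    ct <- cor.test(j$value.x, j$value.y, method = "pearson")
    data.frame(environment = e, n = nrow(j),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
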