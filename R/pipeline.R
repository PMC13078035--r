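#' Pipeline configuration
#'
#' Single configuration object for the end-to-end workflow
#' (simulate -> qc -> blue -> gwas -> tag -> gs -> select -> report). All
#' randomness flows from `seed` through per-stage derived seeds, so a rerun
#' with the same configuration reproduces every artifact.
#'
#' @param outdir output directory for stage artifacts and manifests.
#' @param seed master integer seed.
#' @param sim a [simConfig()] (its own seed is overridden by the derived
#'   simulate-stage seed).
#' @param qc a [qcConfig()].
#' @param ld an [ldConfig()].
#' @param gwasAlphaMode `"fixed"` (the rounded genome-wide cutoff, default)
#'   or `"bonferroni"`.
#' @param gwasFixedP fixed threshold (default 1e-7).
#' @param gwasAlpha family-wise alpha for bonferroni mode (default 0.05).
#' @param powerAlpha significance level for per-SNP power (default 1e-7).
#' @param gsFolds,gsRepeats cross-validation dimensions (defaults 5, 20).
#' @param eliteM elite-set size for the retention analysis (default 12).
#' @param fractions reduction fractions (default c(0.2, 0.3, 0.4, 0.5)).
#' @param nCandidates candidates held out of the reference panel (default
#'   20).
#' @param traitGWAS trait scanned in the GWAS stage (default "OAC").
#' @param traitGS trait predicted in the GS stage (default "SPP").
#' @param environmentsGWAS,environmentsGS environment inclusion lists per
#'   trait (`NULL` = all; GS default `c("E1", "E2", "E3")`, the
#'   uncontaminated trials).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outdir, seed = 1L, sim = simConfig(),
                           qc = qcConfig(), ld = ldConfig(),
                           gwasAlphaMode = c("fixed", "bonferroni"),
                           gwasFixedP = 1e-7, gwasAlpha = 0.05,
                           powerAlpha = 1e-7,
                           gsFolds = 5L, gsRepeats = 20L, eliteM = 12L,
                           fractions = c(0.2, 0.3, 0.4, 0.5),
                           nCandidates = 20L, traitGWAS = "OAC",
                           traitGS = "SPP", environmentsGWAS = NULL,
                           environmentsGS = c("E1", "E2", "E3")) {
  stopifnot(inherits(sim, "SimConfig"), inherits(qc, "QCConfig"),
            inherits(ld, "LDConfig"))
  if (!traitGWAS %in% sim$traitNames || !traitGS %in% sim$traitNames)
    stop("traitGWAS/traitGS must appear in sim$traitNames")
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim, qc = qc,
              ld = ld, gwasAlphaMode = match.arg(gwasAlphaMode),
              gwasFixedP = gwasFixedP, gwasAlpha = gwasAlpha,
              powerAlpha = powerAlpha, gsFolds = as.integer(gsFolds),
              gsRepeats = as.integer(gsRepeats), eliteM = as.integer(eliteM),
              fractions = fractions, nCandidates = as.integer(nCandidates),
              traitGWAS = traitGWAS, traitGS = traitGS,
              environmentsGWAS = environmentsGWAS,
              environmentsGS = environmentsGS)
  class(cfg) <- "PipelineConfig"
  cfg
}

.stageOrder <- c("simulate", "qc", "blue", "gwas", "tag", "gs", "select",
                 "report")

.stageSeed <- function(config, stage) {
  (config$seed * 1009L + match(stage, .stageOrder) * 7919L) %%
    .Machine$integer.max
}

.artifact <- function(config, name) file.path(config$outdir, name)

.needArtifact <- function(config, name, producedBy) {
  p <- .artifact(config, name)
  if (!file.exists(p))
    stop("missing prerequisite '", name, "': run stage '", producedBy,
         "' first")
  p
}

.writeManifest <- function(config, stage, params, inputs, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(packageVersion("TagGS")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = .stageSeed(config, stage),
    parameters = params,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  path <- .artifact(config, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.writeTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run one pipeline stage
#'
#' Stages communicate through plain-text artifacts in `config$outdir`; each
#' stage is individually invocable (prerequisite artifacts are read back
#' from disk), idempotent for a fixed configuration, and writes a JSON
#' manifest recording parameters, input/output file hashes and the derived
#' stage seed. A missing prerequisite raises an error naming the stage that
#' produces it.
#'
#' @param name one of `"simulate"`, `"qc"`, `"blue"`, `"gwas"`, `"tag"`,
#'   `"gs"`, `"select"`, `"report"`.
#' @param config a [pipelineConfig()].
#' @return invisible list of the stage's in-memory results.
#' @export
runStage <- function(name, config) {
  name <- match.arg(name, .stageOrder)
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(config$outdir) &&
      !dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", config$outdir)
  switch(name,
         simulate = .stageSimulate(config),
         qc = .stageQC(config),
         blue = .stageBLUE(config),
         gwas = .stageGWAS(config),
         tag = .stageTag(config),
         gs = .stageGS(config),
         select = .stageSelect(config),
         report = pipelineReport(config))
}

#' Run the full pipeline
#'
#' Executes every stage in order and returns the report.
#'
#' @param config a [pipelineConfig()].
#' @return the report list (also written as `report.json`).
#' @export
runPipeline <- function(config) {
  for (s in .stageOrder) res <- runStage(s, config)
  res
}

.stageSimulate <- function(config) {
  sim <- config$sim
  sim$seed <- .stageSeed(config, "simulate")
  gt <- simulateGenotypes(sim)
  pheno <- simulatePhenotypes(gt$genotypes, gt$truth, sim)
  paths <- writeFixture(gt$genotypes, pheno, gt$truth, config$outdir)
  set.seed(sim$seed + 1L)
  candidates <- sort(sample(sampleIds(gt$genotypes), config$nCandidates))
  candPath <- .artifact(config, "candidates.txt")
  writeLines(candidates, candPath)
  message("simulate: ", length(sampleIds(gt$genotypes)), " accessions, ",
          nrow(markerMap(gt$genotypes)), " SNPs, ",
          length(candidates), " candidates held out")
  .writeManifest(config, "simulate",
                 params = sim[c("nAccessions", "nChromosomes",
                                "snpsPerChromosome", "seed",
                                "missingRate")],
                 inputs = character(),
                 outputs = c(unname(paths), candPath))
  invisible(list(genotypes = gt$genotypes, truth = gt$truth,
                 phenotypes = pheno, candidates = candidates))
}

.readDosageTSV <- function(path, mapPath) {
  d <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE))
  map <- read.table(mapPath, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  GenotypeData(d, map, orient = FALSE)
}

.stageQC <- function(config) {
  vcf <- .needArtifact(config, "genotypes.vcf", "simulate")
  g <- readVCF(vcf)
  res <- applyQC(g, config$qc)
  rep <- res$report
  dosPath <- .writeTSV(
    data.frame(accession = sampleIds(res$genotypes),
               dosageMatrix(res$genotypes), check.names = FALSE),
    .artifact(config, "genotypes_filtered.tsv"))
  mapPath <- .writeTSV(markerMap(res$genotypes),
                       .artifact(config, "marker_map.tsv"))
  qcPath <- .writeTSV(
    data.frame(metric = c("samples_removed", "loci_removed_missing",
                          "loci_removed_maf", "loci_retained"),
               value = c(length(rep$samplesRemoved),
                         length(rep$lociRemoved$missing),
                         length(rep$lociRemoved$maf), rep$lociRetained)),
    .artifact(config, "qc_report.tsv"))
  densPath <- .writeTSV(snpDensity(res$genotypes),
                        .artifact(config, "snp_density.tsv"))
  message("qc: ", rep$lociInput, " loci in, ", rep$lociRetained,
          " retained; ", length(rep$samplesRemoved), " samples removed")
  .writeManifest(config, "qc", params = unclass(config$qc),
                 inputs = vcf,
                 outputs = c(dosPath, mapPath, qcPath, densPath))
  invisible(res)
}

.stageBLUE <- function(config) {
  phPath <- .needArtifact(config, "phenotypes.tsv", "simulate")
  pheno <- read.table(phPath, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  outputs <- character()
  blues <- list()
  for (tn in config$sim$traitNames) {
    envs <- if (tn == config$traitGS) config$environmentsGS
            else config$environmentsGWAS
    b <- computeBLUEs(pheno, tn, environments = envs)
    blues[[tn]] <- b
    outputs <- c(outputs, .writeTSV(
      b, .artifact(config, paste0("blue_", tn, ".tsv"))))
    vc <- fitMultiEnvModel(pheno, tn, environments = envs)
    h2 <- broadSenseH2(vc)
    outputs <- c(outputs, .writeTSV(
      data.frame(component = c("sigma2_g", "sigma2_ge", "sigma2_eps",
                               "n_env", "n_rep", "H2"),
                 value = c(vc$sigma2g, vc$sigma2ge, vc$sigma2eps, vc$nEnv,
                           vc$nRep, h2)),
      .artifact(config, paste0("varcomp_", tn, ".tsv"))))
    outputs <- c(outputs, .writeTSV(
      traitSummary(pheno, tn, environments = envs),
      .artifact(config, paste0("summary_", tn, ".tsv"))))
    outputs <- c(outputs, .writeTSV(
      anovaTable(pheno, tn, environments = envs),
      .artifact(config, paste0("anova_", tn, ".tsv"))))
    message("blue: ", tn, " H2 = ", sprintf("%.4f", h2))
  }
  corTab <- traitCorrelation(pheno, config$sim$traitNames[1],
                             config$sim$traitNames[2],
                             environments = config$environmentsGS)
  outputs <- c(outputs, .writeTSV(
    corTab, .artifact(config, "trait_correlation.tsv")))
  .writeManifest(config, "blue",
                 params = list(environmentsGS = config$environmentsGS),
                 inputs = phPath, outputs = outputs)
  invisible(blues)
}

.stageGWAS <- function(config) {
  dosPath <- .needArtifact(config, "genotypes_filtered.tsv", "qc")
  mapPath <- .needArtifact(config, "marker_map.tsv", "qc")
  bluePath <- .needArtifact(config,
                            paste0("blue_", config$traitGWAS, ".tsv"),
                            "blue")
  candPath <- .needArtifact(config, "candidates.txt", "simulate")
  g <- .readDosageTSV(dosPath, mapPath)
  blue <- read.table(bluePath, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  y <- setNames(blue$blue, blue$accession)
  candidates <- readLines(candPath)
  reference <- setdiff(sampleIds(g), candidates)
  y <- y[intersect(names(y), reference)]

  M <- meanImpute(g)  # frequencies from the combined panel
  grm <- buildGRM(M)
  scan <- scanAssociation(M[names(y), , drop = FALSE], y, K = grm,
                          powerAlpha = config$powerAlpha)
  map <- markerMap(g)
  scan$chrom <- map$chrom[match(scan$snp, map$snp)]
  scan$pos <- map$pos[match(scan$snp, map$snp)]
  scan$maf <- map$maf[match(scan$snp, map$snp)]
  thr <- bonferroniThreshold(sum(scan$tested), alpha = config$gwasAlpha,
                             mode = config$gwasAlphaMode,
                             fixedP = config$gwasFixedP)
  assocPath <- .writeTSV(scan, .artifact(config, "assoc.tsv"))
  thrPath <- .artifact(config, "threshold.json")
  jsonlite::write_json(thr, thrPath, auto_unbox = TRUE, digits = NA)
  qqPath <- .writeTSV(qqTable(scan), .artifact(config, "qq.tsv"))
  manPath <- .writeTSV(manhattanTable(scan),
                       .artifact(config, "manhattan.tsv"))
  grmPath <- .writeTSV(
    data.frame(accession = sampleIds(grm), grmMatrix(grm),
               check.names = FALSE),
    .artifact(config, "grm.tsv"))
  jsonlite::write_json(
    list(denominator = grm@denominator, blendEpsilon = grm@blendEpsilon),
    .artifact(config, "grm_meta.json"), auto_unbox = TRUE, digits = NA)
  nSig <- sum(scan$tested & scan$p <= thr$p)
  message("gwas: ", sum(scan$tested), " SNPs tested (",
          sum(!scan$tested), " skipped), ", nSig,
          " significant at p <= ", format(thr$p))
  .writeManifest(config, "gwas",
                 params = list(alphaMode = config$gwasAlphaMode,
                               threshold = thr$p, n = length(y)),
                 inputs = c(dosPath, mapPath, bluePath, candPath),
                 outputs = c(assocPath, thrPath, qqPath, manPath, grmPath,
                             .artifact(config, "grm_meta.json")))
  invisible(list(scan = scan, threshold = thr, grm = grm))
}

.stageTag <- function(config) {
  assocPath <- .needArtifact(config, "assoc.tsv", "gwas")
  thrPath <- .needArtifact(config, "threshold.json", "gwas")
  dosPath <- .needArtifact(config, "genotypes_filtered.tsv", "qc")
  mapPath <- .needArtifact(config, "marker_map.tsv", "qc")
  bluePath <- .needArtifact(config,
                            paste0("blue_", config$traitGWAS, ".tsv"),
                            "blue")
  scan <- read.table(assocPath, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  thr <- jsonlite::read_json(thrPath, simplifyVector = TRUE)
  g <- .readDosageTSV(dosPath, mapPath)
  hits <- scan$snp[scan$tested & !is.na(scan$p) & scan$p <= thr$p]
  outputs <- character()
  if (length(hits) < 1) {
    blocks <- list()
    validation <- list(note = "no blocks: no significant SNPs")
    message("tag: no significant SNPs; no blocks")
  } else {
    blocks <- detectBlocks(g, hits, config$ld,
                           seed = .stageSeed(config, "tag"))
    blocks <- selectTags(blocks, g, config$ld)
    blue <- read.table(bluePath, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    phPath <- .artifact(config, "phenotypes.tsv")
    phenoTable <- if (file.exists(phPath))
      read.table(phPath, sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE) else NULL
    tags <- vapply(blocks, `[[`, character(1), "tag")
    val <- validateTagsRegression(g, tags,
                                  setNames(blue$blue, blue$accession),
                                  phenoTable = phenoTable,
                                  trait = config$traitGWAS)
    validation <- list(tags = tags, adjustedR2 = val$adjustedR2,
                       perEnvAdjustedR2 = as.list(val$perEnvAdjustedR2),
                       coefficients = as.list(val$coefficients),
                       n = val$n)
    message("tag: ", length(hits), " significant SNPs -> ",
            length(blocks), " blocks; overall adjusted R2 = ",
            sprintf("%.4f", val$adjustedR2))
  }
  blockPath <- .writeTSV(blocksTable(blocks),
                         .artifact(config, "blocks.tsv"))
  valPath <- .artifact(config, "tag_validation.json")
  jsonlite::write_json(validation, valPath, auto_unbox = TRUE, digits = NA)
  outputs <- c(blockPath, valPath)
  .writeManifest(config, "tag", params = unclass(config$ld)[
    c("tagR2", "tagWindowBp", "representativeWindowBp", "blockMethod")],
    inputs = c(assocPath, thrPath, dosPath, mapPath),
    outputs = outputs)
  invisible(list(blocks = blocks, validation = validation))
}

.stageGS <- function(config) {
  grmPath <- .needArtifact(config, "grm.tsv", "gwas")
  bluePath <- .needArtifact(config, paste0("blue_", config$traitGS, ".tsv"),
                            "blue")
  candPath <- .needArtifact(config, "candidates.txt", "simulate")
  grmTab <- read.table(grmPath, sep = "\t", header = TRUE,
                       row.names = 1, check.names = FALSE)
  meta <- jsonlite::read_json(.artifact(config, "grm_meta.json"),
                              simplifyVector = TRUE)
  G <- as.matrix(grmTab)
  dimnames(G) <- list(rownames(grmTab), rownames(grmTab))
  grm <- methods::new("GRM", matrix = G, sampleIds = rownames(G),
                      denominator = meta$denominator,
                      blendEpsilon = meta$blendEpsilon)
  blue <- read.table(bluePath, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  y <- setNames(blue$blue, blue$accession)
  candidates <- readLines(candPath)
  reference <- setdiff(names(y), candidates)

  fit <- suppressWarnings(fitGBLUP(grm, y, phenotypedIds = reference))
  cv <- suppressWarnings(crossValidate(
    grm, y[reference], folds = config$gsFolds, repeats = config$gsRepeats,
    seed = .stageSeed(config, "gs")))
  gebvPath <- .writeTSV(
    data.frame(accession = names(gebv(fit)), gebv = unname(gebv(fit)),
               phenotyped = unname(fit@phenotyped)),
    .artifact(config, "gebv.tsv"))
  fitPath <- .artifact(config, "gs_fit.json")
  jsonlite::write_json(
    list(sigma2_a = fit@sigma2a, sigma2_e = fit@sigma2e, k = fit@k,
         h2_narrow = narrowH2(fit), boundary = fit@boundary,
         blendEpsilon = fit@blendEpsilon),
    fitPath, auto_unbox = TRUE, digits = NA)
  cvPath <- .artifact(config, "cv_metrics.json")
  jsonlite::write_json(
    list(predictive_ability = cv$predictiveAbility, accuracy = cv$accuracy,
         h2_narrow = cv$h2Narrow, folds = cv$folds, repeats = cv$repeats,
         seed = cv$seed),
    cvPath, auto_unbox = TRUE, digits = NA)
  message("gs: h2 = ", sprintf("%.4f", narrowH2(fit)),
          ", predictive ability = ", sprintf("%.4f", cv$predictiveAbility),
          ", accuracy = ", sprintf("%.4f", cv$accuracy))
  .writeManifest(config, "gs",
                 params = list(folds = config$gsFolds,
                               repeats = config$gsRepeats),
                 inputs = c(grmPath, bluePath, candPath),
                 outputs = c(gebvPath, fitPath, cvPath))
  invisible(list(fit = fit, cv = cv))
}

.stageSelect <- function(config) {
  gebvPath <- .needArtifact(config, "gebv.tsv", "gs")
  bluePath <- .needArtifact(config, paste0("blue_", config$traitGS, ".tsv"),
                            "blue")
  candPath <- .needArtifact(config, "candidates.txt", "simulate")
  gtab <- read.table(gebvPath, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  blue <- read.table(bluePath, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  candidates <- readLines(candPath)
  ge <- setNames(gtab$gebv, gtab$accession)[candidates]
  ph <- setNames(blue$blue, blue$accession)[candidates]
  ret <- retentionAnalysis(ge, ph, m = config$eliteM,
                           fractions = config$fractions)
  corr <- gebvPhenotypeCorrelation(ge, ph)
  retPath <- .writeTSV(as.data.frame(ret),
                       .artifact(config, "retention.tsv"))
  corPath <- .artifact(config, "gebv_phenotype_correlation.json")
  jsonlite::write_json(corr, corPath, auto_unbox = TRUE, digits = NA)
  message("select: retention at ",
          paste(sprintf("%.0f%%", 100 * ret$fraction), collapse = "/"),
          " reduction = ",
          paste(sprintf("%.1f%%", 100 * ret$retention_rate),
                collapse = "/"), "; r(GEBV, phenotype) = ",
          sprintf("%.4f", corr$r))
  .writeManifest(config, "select",
                 params = list(m = config$eliteM,
                               fractions = config$fractions),
                 inputs = c(gebvPath, bluePath, candPath),
                 outputs = c(retPath, corPath))
  invisible(list(retention = ret, correlation = corr))
}

#' Collate pipeline artifacts into a machine-readable report
#'
#' Reads whatever stage artifacts exist in `config$outdir` and writes
#' `report.json` summarizing trait statistics and heritabilities,
#' significant SNPs, haplotype blocks and tags (stating "no blocks" when
#' the scan found nothing), GS variance components, cross-validation
#' metrics and the retention table.
#'
#' @param config a [pipelineConfig()] (or a string: the output directory of
#'   a previous run, with default settings assumed).
#' @return the report list, invisibly; also written as `report.json`.
#' @export
pipelineReport <- function(config) {
  if (is.character(config)) config <- pipelineConfig(outdir = config)
  out <- config$outdir
  report <- list(package_version = as.character(packageVersion("TagGS")),
                 seed = config$seed)
  grab <- function(name) {
    p <- file.path(out, name)
    if (file.exists(p))
      read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    else NULL
  }
  grabJson <- function(name) {
    p <- file.path(out, name)
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
    else NULL
  }
  traits <- config$sim$traitNames
  report$trait_summaries <- lapply(
    setNames(traits, traits),
    function(tn) grab(paste0("summary_", tn, ".tsv")))
  report$variance_components <- lapply(
    setNames(traits, traits),
    function(tn) grab(paste0("varcomp_", tn, ".tsv")))
  report$trait_correlation <- grab("trait_correlation.tsv")
  thr <- grabJson("threshold.json")
  assoc <- grab("assoc.tsv")
  if (!is.null(assoc) && !is.null(thr)) {
    sig <- assoc[assoc$tested & !is.na(assoc$p) & assoc$p <= thr$p, ]
    report$gwas <- list(threshold = thr, n_tested = sum(assoc$tested),
                        n_significant = nrow(sig),
                        significant = sig)
  }
  blocks <- grab("blocks.tsv")
  report$tags <- if (is.null(blocks) || !nrow(blocks))
    list(note = "no blocks") else
    list(blocks = blocks, validation = grabJson("tag_validation.json"))
  report$gs <- grabJson("gs_fit.json")
  report$cv <- grabJson("cv_metrics.json")
  report$retention <- grab("retention.tsv")
  report$gebv_phenotype_correlation <-
    grabJson("gebv_phenotype_correlation.json")
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}
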