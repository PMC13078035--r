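# Shared simulated fixtures, built once per test run and memoized.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]]))
    .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

majorQtlOn <- function(chrom, pos = 5e5, effect = 10)
  data.frame(chrom = chrom, pos = pos, effect = effect, mode = "recessive",
             stringsAsFactors = FALSE)

# default-sized panel: 169 accessions x 2000 SNPs, both traits
panelSim <- function() fixture("panel", function() {
  cfg <- simConfig(seed = 11)
  sim <- simulateGenotypes(cfg)
  sim$pheno <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
  sim$config <- cfg
  sim
})

# complete (no missingness) polygenic panel for GRM/GBLUP work
polyPanel <- function() fixture("poly", function() {
  cfg <- simConfig(seed = 21, missingRate = 0, nMinorQtl = 300,
                   majorQtl = majorQtlOn("Chr09"))
  sim <- simulateGenotypes(cfg)
  sim$grm <- buildGRM(sim$genotypes)
  sim$config <- cfg
  sim
})

# single-chromosome fixture with exactly 3 founder LD blocks
threeBlockSim <- function(mutation = 0, seed = 13) {
  cfg <- simConfig(nAccessions = 200, nChromosomes = 1,
                   snpsPerChromosome = 30, chromosomeLengthBp = 2.4e5,
                   blockLengthBp = 8e4, blockMutationRate = mutation,
                   mafRange = c(0.2, 0.5), missingRate = 0,
                   majorQtl = majorQtlOn("Chr01", 1e5), seed = seed)
  simulateGenotypes(cfg)
}

# GenotypeData from a bare dosage matrix on one chromosome
toyGenotypes <- function(dosages, pos = NULL, chrom = "Chr01") {
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 1000L
  GenotypeData(dosages,
               data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                          stringsAsFactors = FALSE))
}
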