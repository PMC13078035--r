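---
title: "Dual-trait breeding analysis with TagGS: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-trait breeding analysis with TagGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TagGS)
```

TagGS implements the quantitative backbone of a breeding program that
improves two traits with very different genetic architectures at once: a
major-gene quality trait (the motivating case is kernel oleic acid content,
OAC, governed largely by recessive major-effect loci) handled by
marker-assisted selection on tag SNPs, and a low-heritability yield trait
(single-plant productivity, SPP) handled by genomic selection. This
vignette explains each model, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was open.

## The multi-environment phenotype model

Observations from a randomized complete block design repeated across
environments are modelled with environments and replicates-within-
environments as fixed effects and genotypes and genotype-by-environment
(G×E) interactions as random effects. `fitMultiEnvModel()` obtains REML
estimates of $\sigma^2_g$, $\sigma^2_{ge}$ and $\sigma^2_\varepsilon$
through `lme4::lmer`; on balanced data these coincide with the classical
expected-mean-squares estimator, which the test suite uses as an
independent oracle. Components estimated at the zero boundary are reported
as 0 and flagged, since downstream formulas assume non-negative variances.

Broad-sense heritability on an entry-mean basis is
$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/n +
\sigma^2_\varepsilon/(nr)},$$
with $n$ environments and $r$ replicates. It increases in $\sigma^2_g$,
$n$ and $r$ and decreases in the two noise components; the suite asserts
this monotonicity numerically. A caution for users interpreting recovery
simulations: when the single-plot heritability is low (large
$\sigma^2_\varepsilon$), the sampling standard deviation of $\hat H^2$ at
170–200 genotypes and 3×3 trial dimensions is about 0.06, so individual
estimates routinely deviate by more than 0.08 from the truth even though
the median error stays under 0.04.

BLUEs are computed in a single fixed-effects least-squares fit
(`value ~ accession + environment + environment:replicate`), with the BLUE
of an accession defined as its fitted value averaged over every
environment–replicate cell. On balanced data this equals the genotype mean
up to a common constant. A two-stage means approach would give the same
answer on balanced data but degrades under unbalance, which is why the
single-fit form is used. Terms that do not vary (a single environment or
replicate) are dropped automatically; genuinely confounded designs are an
error rather than a silent aliased fit.

Environment inclusion is a configuration list, not a constant: yield
trials contaminated by disease pressure can be excluded per trait (the
pipeline default keeps environments E1–E3 for the yield trait and all four
for the quality trait).

## Genotype handling and QC

`GenotypeData` extends `RangedSummarizedExperiment`: SNPs are rows with
genomic coordinates, accessions are columns, and the single `dosage` assay
counts copies of the minor allele (0/1/2, `NA` missing). Orientation to
the minor allele is enforced at construction; a 50/50 frequency tie is
canonically counted on the ALT allele so that write/read round-trips are
bit-identical.

QC applies, in a fixed order: samples with missingness strictly above 10%,
then loci with missingness strictly above 10% (computed on surviving
samples), then loci with MAF strictly below 1% after recomputing
frequencies on survivors. The order changes results on structured
missingness and is therefore part of the documented contract, as are the
strict inequalities (a locus at exactly 10% missingness survives). SNP
density uses non-overlapping, half-open, 1-anchored windows; overlapping
("sliding") windows were rejected so that window counts conserve the SNP
total. Mean imputation (locus mean of observed dosages) is the only
missing-data treatment, applied just before linear algebra that requires a
complete matrix; loci with no observations at all are a QC failure, not an
imputation case.

## Mixed-model GWAS with analytic power

The association scan is a mixed linear model with a genomic relationship
matrix as the kinship correction:
$y = \mu + x\beta + u + e$, $u \sim N(0, \sigma^2_g K)$. The
residual-to-genetic variance ratio $\delta$ is estimated once on the null
model by spectral REML (eigendecomposition of $K$, 1-D optimization of the
restricted likelihood in $\delta$) and reused for every SNP — the standard
one-ratio approximation; per-marker refits change little at these sample
sizes and cost a full REML per SNP. Each SNP is then tested by generalized
least squares in the whitened space with a 1-df Wald chi-square. With
$K = I$ the scan provably reduces to ordinary least squares, which the
suite asserts against a per-SNP `lm()` oracle, and under a simulated null
with kinship the empirical type-I error at 0.05 is within ±0.01.

Two open definitions were fixed as follows:

* **PVE.** The per-SNP proportion of variance explained is the squared
  partial correlation between dosage and phenotype in the kinship-whitened
  space. It is monotone in the Wald statistic at fixed $n$ and recovers a
  constructed 25% effect within ±0.05 in simulation, which is the
  justification offered for this definition.
* **Threshold.** Both modes are provided: exact Bonferroni $\alpha/N$ and
  a fixed rounded genome-wide cutoff ($10^{-7}$, i.e. $-\log_{10}p = 7$);
  the pipeline default is the fixed mode.

Statistical power for a significant SNP uses the noncentral chi-square
approach: $\mathrm{NCP} = n R^2/(1-R^2)$ and
$\mathrm{power} = P[\chi^2_1(\mathrm{NCP}) > q_{1-\alpha}]$ with
$q_{1-\alpha}$ the central quantile at the significance threshold
(default $\alpha = 10^{-7}$, df = 1 for the single-SNP additive test). At
$R^2 = 0$ this equals $\alpha$ exactly. With $n = 149$ the endpoints of
the PVE range 17.65–26.23% give powers 0.63 and 0.97 at two decimals.

## LD, haplotype blocks and tag SNPs

Because inputs are unphased dosages, $r^2$ is the genotype-level composite
measure: the squared Pearson correlation of dosage vectors. This differs
from haplotype $r^2$ in principle but is phase-free and is the quantity
the tagging logic consumes. $D'$ is estimated by the classic two-locus EM
under Hardy–Weinberg equilibrium and normalized by its frequency bound;
the EM's HWE assumption is questionable in heavily selfed material, which
is flagged here, while $r^2$ is unaffected. A brute-force likelihood
maximization over the one free haplotype frequency serves as the test
oracle.

Block detection (default `r2_cluster`) forms an edge between two candidate
SNPs when they are on one chromosome, within 250 kb, and at $r^2 \ge 0.8$,
then takes connected components — single linkage, mirroring the logic of
standard taggers. The output partitions the input; singletons are
singleton blocks. A `dprime_ci` mode (bootstrap percentile CI on $D'$ with
strong-LD bounds) is provided as the alternative family of block callers,
but only the $r^2$ mode carries truth-recovery guarantees on synthetic
fixtures. The tag of a block is the member with the highest mean $r^2$ to
its block mates within a 500 kb representative window, ties broken toward
the smallest position so selection is deterministic and order-invariant.

Tag panels are validated two ways: multiple OLS regression of the
phenotype on 0/1/2-encoded tags (adjusted $R^2$, overall and per
environment) and per-genotype-class comparisons with a Welch t-test
between homozygote classes (heterozygotes reported, untested by default;
zero-variance comparisons flagged degenerate).

## GBLUP genomic selection

The VanRaden relationship matrix is $G = ZZ'/(2\sum_i p_i(1-p_i))$ with
$Z$ the dosage matrix centred by twice the allele frequency. Frequencies
come from the full combined panel — reference plus candidates — so that
candidate genotypes inform the centring, and a small ridge
(`blendEpsilon`, default $10^{-6}$) makes $G$ invertible and is recorded
in the object and every downstream fit.

`fitGBLUP()` estimates $\sigma^2_a$ and $\sigma^2_e$ by the same spectral
REML on the phenotyped submatrix, then solves Henderson's mixed-model
equations with $k = \sigma^2_e/\sigma^2_a$ jointly over *all* accessions,
so $\hat u$ contains GEBVs for unphenotyped candidates directly. The joint
MME and the two-step partition form
$G_{cp}G_{pp}^{-1}\hat u_p$ are equivalent under the model; the suite
verifies the MME against a dense closed-form BLUP oracle on small systems
rather than trusting the equivalence. Narrow-sense heritability is
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$.

Cross-validation is repeated k-fold (default 5 folds × 20 repeats), with
seeded uniform fold assignment, no stratification (deliberately — the
reference panel is a single population), variance components refit per
fold by default (switchable to reuse the full-data ratio), and folds that
would hold out fewer than 3 accessions merged with a warning. Predictive
ability is the mean held-out Pearson $r(\mathrm{GEBV}, Y_c)$; accuracy is
predictive ability divided by $\sqrt{h^2}$ from the full-data fit. Note an
arithmetic subtlety users may meet in the literature: a predictive ability
of 0.3320 with $h^2 = 0.3377$ implies accuracy 0.571, while rounding
conventions elsewhere may print 0.58; the package emits the unrounded
ratio.

The retention tool ranks candidates: elites are the top-$m$ (default 12)
by phenotype — a "breeding retention value" secondary criterion sometimes
mentioned alongside phenotype ranking is undefined and deliberately not
implemented — and for each reduction fraction $f$ the $\lfloor fN \rfloor$
lowest-GEBV candidates are culled. Ties in either ranking break by
accession id. Under GEBV–phenotype independence the expected retention at
$N = 20$, $m = 12$, $f = 0.3$ is the hypergeometric mean $14/20 = 70\%$,
which the suite confirms by simulation; perfectly anti-correlated rankings
give exactly 50% at $f = 0.3$.

## The synthetic population generator

`simulateGenotypes()` builds LD by founder-mosaic copying, not coalescent
simulation: each chromosome is cut into fixed blocks (default 100 kb);
each founder (default 16) carries one of two block haplotype labels whose
frequency is drawn from the configured MAF range; SNP alleles deviate from
the label at a small per-SNP rate (default 0.02); and each gamete copies a
uniformly chosen founder per block. This yields high within-block $r^2$
that collapses to the finite-sample floor across block boundaries —
exactly the structure tag-SNP selection assumes — plus ground truth
(founder haplotypes, per-SNP block ids, QTL effects, true breeding values)
for recovery tests. Defaults mirror the study conditions: 169 accessions,
20 chromosomes, two recessive major-effect QTL for the quality trait on
chromosomes 9 and 19 (effects 10 and 8 on a ~65-unit scale, mapped to the
nearest common SNP so the minor-homozygote class is populated), 30 minor
additive QTL per trait, heritability targets 0.96 and 0.45, 4 environments
× 3 replicates, 2% genotype missingness. SNP counts are desk-scaled (100
per chromosome by default, 2000 genome-wide) — dense enough for block
structure and GRM work while keeping a full pipeline run in seconds;
nothing in the methods depends on marker density beyond LD coverage.

Phenotypes are grand mean + environment effect + replicate-within-
environment effect + centred genetic value + G×E draw + residual, with
G×E variance a configured fraction of genetic variance (default 0.008,
a deliberately small interaction consistent with the motivating program)
and the residual scaled so the $H^2$ formula hits its target in
expectation. Environment and replicate effects are drawn once per
simulation and recorded in attributes, making BLUE recovery exactly
checkable. Environment main-effect magnitude is not pinned by any external
source; the default (variance 25% of genetic variance) was chosen once as
a realistic multi-location spread and is a free parameter. Trait
correlation is targeted at zero by giving the two traits disjoint QTL
sets; residual LD between QTL induces only small realized correlations
(the suite bounds them at |r| < 0.2).

What the generator does **not** emulate: allotetraploid subgenome
homoeology, selection and drift dynamics, pedigree structure, spatial
field trends, and non-uniform missingness. Passing recovery tests on these
fixtures therefore demonstrates correctness of the estimators under the
stated model, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* REML in $\delta$ is maximized on a 120-point log grid over
  $[10^{-5}, 10^5]$ refined by Brent optimization; if the restricted
  likelihood is flat (kinship proportional to the identity) the ratio is
  unidentifiable, a warning is raised and the boundary value is returned
  with a degenerate flag.
* Non-PSD kinship inputs are rejected with advice to blend, rather than
  silently clipped.
* Monomorphic SNPs are flagged and skipped by the scan; all-monomorphic
  panels are a zero-denominator error for the GRM.
* Zero-variance class comparisons report p at the machine floor (different
  means) or 1 (equal means) with a degenerate flag instead of erroring.
* All pipeline randomness derives from one master seed through fixed
  per-stage offsets; reruns reproduce every artifact byte-for-byte
  (manifests differ only in timestamps).

## Problem sizes used in the shipped checks

Simulation-backed tests run at 150–200 accessions and 200–2000 SNPs, with
20-seed Monte-Carlo loops for parameter recovery, 500 aggregated
replicates for null calibration of the scan, and 2000 replicates for the
retention null — sizes chosen so the whole suite and the acceptance script
each complete in about a minute on a single CPU while keeping Monte-Carlo
error well inside the asserted tolerances.

## Known limitations

REML heritability estimates inherit the relatedness of the panel: with few
founders the effective number of independent genotypes is smaller than the
accession count, widening sampling spread relative to iid expectations.
Genomic prediction accuracy on the synthetic panel is governed by the
founder-segment structure and can sit well below values reported for real
programs with tighter reference–candidate relatedness; the package asserts
the theoretical bound (predictive ability $\le \sqrt{h^2}$ plus
Monte-Carlo error) rather than any particular accuracy level. The D' EM
assumes random mating; for predominantly selfing crops treat D'-based
block calls as descriptive and prefer the $r^2$ mode, which is the
default.
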