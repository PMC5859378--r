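---
title: "Genomic evaluation of juvenile growth in a partial factorial carp cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation of juvenile growth in a partial factorial carp cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`carpgs` implements a complete genomic-evaluation workflow for juvenile
growth in common carp (*Cyprinus carpio*) bred by partial factorial mating,
together with a synthetic-data generator that reproduces the statistical
structure such an experiment produces. This vignette is the package's
account of the underlying models, the choices that were genuinely open, and
what the simulation-based checks do and do not demonstrate.

## The animal model

Every estimation step rests on the linear mixed "animal model"

$$y = Xb + Zu + e, \qquad u \sim N(0,\, K\sigma_g^2), \qquad e \sim N(0,\, I\sigma_e^2),$$

where $y$ are phenotypes (body weight in g or standard length in mm), $b$
contains the fixed effect of the four-level factorial cross, $u$ is the
vector of additive genetic values, and $K$ is either the pedigree numerator
relationship matrix $A$ (built by the tabular method, so `a_ii = 1 + F_i`)
or the VanRaden method-1 genomic relationship matrix
$G = ZZ'/(2\sum_j p_j(1-p_j))$ with dosages centred by twice the observed
allele frequencies and missing dosages mean-imputed. Narrow-sense
heritability is $h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$. The
bivariate version puts 2×2 genetic and residual covariance matrices on the
two traits and reports the genetic correlation
$r_g = \sigma_{g,12}/(\sigma_{g,1}\sigma_{g,2})$.

`animal_model()` fits this model by restricted maximum likelihood with
average-information (AI) updates. All computations run in the eigenbasis of
$K$: after rotating $y$ and $X$ by the eigenvectors, the phenotypic
covariance is diagonal (univariate) or block-diagonal in 2×2 blocks
(bivariate), so likelihood, scores, the AI matrix and BLUP predictions are
all linear-time expressions per iteration. AI steps are projected onto the
parameter space (components floored at $10^{-8}\sigma_P^2$); if a projected
step does not increase the likelihood after step-halving, an
expectation-maximisation update — always uphill, always inside the space —
is taken instead. Convergence requires a relative parameter change below
`tol` (default `1e-8`). Standard errors come from the inverse AI matrix,
with $h^2$ and $r_g$ standard errors by the delta method; a component at
its boundary reports `NA` standard errors. In the bivariate fit a proposal
outside the positive-semidefinite cone is projected back by eigenvalue
clipping.

Breeding values for *all* individuals carried in $K$ — including
unphenotyped ones — are the BLUPs
$\hat u = \sigma_g^2 K_{\cdot,p} V^{-1}(y - X\hat b)$; this is also how
validation animals are predicted in cross-validation, equivalently to
solving Henderson's mixed-model equations (`solve_mme()`, which is also
exercised directly against hand-inverted systems in the tests).

## The synthetic population

The study design being emulated: four factorial blocks, each mating 5 dams
× 10 sires; about 1,425 offspring in up to 200 full-sib families; a
50-linkage-group genome of ~3,944 cM carrying 12,311 mapped SNPs; bivariate
weight/length phenotypes with heritabilities 0.26 and 0.33, genetic
correlation 0.94 and phenotypic correlation 0.93. `sim_config()` defaults
encode exactly these values.

Generator components, in order:

* **Genome** (`genome_template()`): linkage-group lengths are fixed to the
  printed consensus-map integers (their sum, 3,946 cM, differs from the
  printed 3,944 total by rounding); markers are apportioned to groups
  proportionally to the printed per-group marker counts
  (largest-remainder, at least one per group), QTL proportionally to
  genetic length; positions are uniform within groups. QTL positions are
  distinct from marker positions (default 2,000 QTL), so markers tag QTL
  through linkage only — RAD markers are not causal variants.
* **Founders** (`simulate_founders()`): per-locus allele frequencies drawn
  uniformly on (0.01, 0.5); haplotypes are independent Bernoulli draws, so
  founders are unrelated and in linkage equilibrium by default. An optional
  ancestral burn-in (`founder_generations`, `founder_ne`) mates a base
  population at random for a chosen number of generations before drawing
  the founders, building the short-range LD and co-ancestry of a closed
  hatchery strain; see "What the defaults cannot show" below for why the
  default stays at 0.
* **Mating** (`mate_partial_factorial()`): offspring counts over the 50
  sire×dam pairs per block follow a Dirichlet-multinomial. The
  concentration (default 5) was set so family sizes span roughly 1–21 with
  mean ≈7 and SD ≈4, the spread reported for the assigned families of the
  real cross; draws are repeated until every parent contributes.
* **Gene drop** (`gene_drop()`): meioses use a Haldane crossover process —
  Poisson crossover counts with mean length/100 per linkage group, uniform
  positions, no interference. The real map's distances were produced with
  the Kosambi mapping function, but a gene-dropping simulator needs a
  crossover *process*, not a mapping function; Haldane is the process whose
  map function is exact under no interference, and at the ~0.3 cM marker
  spacing here the difference is immaterial.
* **Phenotypes** (`simulate_phenotypes()`): QTL effects are bivariate
  normal across traits with correlation $r_g$, summed over QTL dosages and
  rescaled so the additive variance among offspring equals
  $h^2\sigma_P^2$ per trait exactly. The residual correlation is solved
  from $r_p\sigma_{Pw}\sigma_{Pl} = r_g\sigma_{gw}\sigma_{gl} +
  r_e\sigma_{ew}\sigma_{el}$ (an impossible $(r_p, r_g, h^2)$ triple is
  rejected with an error naming it). A random cross effect with SD
  0.25 σP per trait is added; the magnitude of the real cross effect is
  unreported, and 25% of a phenotypic SD is a moderate batch effect for
  pond-reared cohorts. Block effects are correlated $r_p$ across the two
  traits, treating a block's growing conditions as acting on body size as
  a whole, which keeps the realized weight–length correlation at its
  target.
* **Noise** (`apply_genotyping_noise()`): genotypes are set missing with
  probability 0.05 and otherwise replaced by a different dosage (uniform
  over the two alternatives) with probability 0.01. These defaults sit
  well below the 4% overall-error allowance used in parentage assignment
  and are typical of RAD genotyping after depth filters.

Residuals are independent across individuals: there is no full-sib
common-environment component. The real experiment incubated each mating
separately before pooling at the swimming stage, so a small early $c^2$
cannot be excluded there; modelling it is out of scope here, which matters
when comparing absolute prediction accuracies (below).

## Quality control and parentage

`filter_genotypes()` applies the study's filters in a fixed, recorded
order: samples with more than 25% missing genotypes are dropped first, then
loci with MAF < 0.01, loci with more than 25% missing calls, and loci
deviating from Hardy–Weinberg proportions in the *parental* samples at
p < 1e-06 (plain 1-df chi-square without continuity correction — the
original QC cites only a p-value threshold). MAF is computed on all
genotyped animals. `maf_threshold_panels()` builds the density scenarios as
loci with MAF *strictly above* each threshold, so panels are nested.

`assign_parentage()` evaluates every candidate sire×dam pair for every
offspring by the trio Mendelian-incompatibility rate: a locus counts iff
all three genotypes are non-missing, and mismatches iff the offspring
dosage cannot arise from one gamete per parent (dosage 0 → gamete 0,
1 → either, 2 → gamete 1). The compiled scan makes the full
1,425 × 800-pair × 12k-locus search a matter of a minute. An offspring is
uniquely assigned iff its best pair's rate is at most the tolerance
(default 0.04, mirroring the overall genotyping-error allowance) *and* the
runner-up pair is worse by at least the uniqueness margin (default 0.01 —
the original report says "uniquely assigned" without quantifying
uniqueness; exact ties are never assigned). All cross-block pairs are
candidates because family structure was unknown at sampling time.
`validate_pedigree()` re-checks assigned links by parent–offspring
opposing-homozygote rates.

## GWAS

`gwas_scan()` uses the two-step mixed-model strategy: variance components
are estimated once under the null model, then each SNP enters as a fixed
effect and is Wald-tested by generalized least squares with the covariance
fixed — the standard single-marker acceleration, which the tests verify
against exact per-SNP REML refits. The polygenic term uses $G$ by default
(the relationship source of the original scan is unstated; $G$ is the
safer control for cryptic structure and is configurable). Genome-wide
significance is Bonferroni, 0.05/N over tested (polymorphic) SNPs. Under
the study-matched polygenic simulation the scan is calibrated
($\lambda_{GC} \in [0.9, 1.1]$, no significant SNPs); ablating the
polygenic term inflates $\lambda_{GC}$ well above 1.2, confirming that the
relationship control is doing the work.

## Cross-validated prediction accuracy

`make_folds()` reproduces the printed splitting convention: a random
permutation is cut into five contiguous validation blocks of
`floor(n/5)`; the remainder individuals join every training set. For the
1,214 evaluated animals this yields exactly 972 training / 242 validation.
Per fold, variance components are re-estimated on the training records (no
leakage; a fixed-components mode reproduces the plausible original
behaviour of estimating once), the MME are solved, and validation animals
are scored by

$$\text{accuracy} = \mathrm{cor}(\widehat{EBV}, y)/h, \qquad
  \text{bias} = \text{OLS slope of } y \text{ on } \widehat{EBV}.$$

Accuracy is computed within fold and averaged; the scenario SE is the SD of
the ten repeat means. In `density_scenarios()` (full density, each MAF
panel, PBLUP — all sharing fold memberships for paired comparison) the $h$
in the denominator is a *single* full-data REML estimate taken from the
full-density genomic fit. This is a deliberate choice: with per-model
per-fold $h$, each relationship matrix scales heritability differently, and
the resulting "accuracies" are not comparable across scenarios — in trial
runs sparse panels could nominally beat full density purely through their
smaller $\hat h^2$. A single $h$ matches how the original comparison
divides every method by the square root of the one reported heritability.
PBLUP uses the pedigree reconstructed by `assign_parentage()`, not the
simulator's truth, so assignment errors propagate realistically.

## Problem sizes used by the checks

The packaged checks run the generator at full study scale (1,425
offspring, 12,311 markers, 2,000 QTL) for the end-to-end pipeline and the
association scan; heritability-recovery uses one study-scale mating design
with 50 phenotype replicates per generating value drawn directly from
$u \sim N(0, A\sigma_g^2)$; module tests use a 250-offspring, 600-marker
population. All stochastic checks fix their seeds.

## What the defaults cannot show

Two printed results of the real experiment are *not* reproduced by this
generator, and deliberately so:

* **The absolute GBLUP accuracy (~0.71) and its ~18% advantage over
  PBLUP.** With linkage-equilibrium founders, marker–QTL LD exists only
  within the two-generation pedigree, so genomic prediction can improve on
  the pedigree only through realized-relationship deviations (full sibs
  share 50% of their genome only on average). Across seeds this yields
  full-density GBLUP accuracies near 0.55–0.60 against PBLUP near
  0.52–0.57 — a 5–8% advantage. The real population is a closed hatchery
  strain whose founders carry ancestral LD, letting markers tag QTL across
  families; early shared rearing may further inflate the apparent accuracy
  of family-structured predictors. The ancestral burn-in option adds LD,
  but at these founder numbers it simultaneously creates founder
  co-ancestry that the pedigree $A$ (which assumes unrelated founders)
  mis-states and drifts allele frequencies, and in measured runs it did
  not close the gap; the default therefore stays at the cleaner
  linkage-equilibrium model, and the accuracy comparison should be read as
  a *relative* one.
* **The exact panel sizes of the MAF scenarios.** The uniform founder MAF
  law is flatter than the real RAD spectrum, so, e.g., the MAF > 0.45
  panel holds ~1,250 simulated SNPs against the printed 530.

Everything else — heritabilities and genetic correlation, parentage
recovery, QC behaviour, GWAS calibration, fold conventions, bias near 1,
and the orderings across marker densities — is reproduced and asserted by
the test suite.

## A worked example

```{r, eval = FALSE}
library(carpgs)

cfg <- sim_config(n_offspring = 300, n_markers = 1000, n_qtl = 200, seed = 1)
pop <- simulate_population(cfg)

qc <- filter_genotypes(pop$genotypes_obs, pop$founder_ids)
asg <- assign_parentage(qc$genotypes[pop$offspring_ids, ],
                        qc$genotypes[pop$sire_ids, ],
                        qc$genotypes[pop$dam_ids, ])
ped <- assignment_pedigree(asg)

G <- condition_relmat(vanraden_grm(qc$genotypes[pop$offspring_ids, ]))
fit <- animal_model(length_mm ~ cross, pop$phenotypes, G)
summary(fit)

sch <- make_folds(pop$offspring_ids, 5, 10, seed = 1)
cv <- density_scenarios(length_mm ~ cross, pop$phenotypes,
                        qc$genotypes[pop$offspring_ids, ],
                        pedigree = ped, thresholds = c(0.3, 0.45),
                        scheme = sch)
print(cv)
```
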