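# carpgs

Genomic evaluation of juvenile growth in common carp (*Cyprinus carpio*)
bred by partial factorial mating — and a synthetic-data generator that
reproduces the statistical structure of such an experiment, so that every
stage of the evaluation can be exercised and checked without any external
data.

The package is aimed at quantitative geneticists and aquaculture-breeding
researchers who want a self-contained, testable reference implementation of
the standard genomic-selection workflow for a family-structured fish
population:

1. **Simulation** — 4 factorial blocks of 5 dams × 10 sires, ~1,425
   offspring in overdispersed full-sib families, a fixed 50-linkage-group
   genome (~3,944 cM, 12,311 SNPs), gene drop with Haldane recombination,
   and bivariate weight/length phenotypes with h² = 0.26/0.33, genetic
   correlation 0.94 and phenotypic correlation 0.93.
2. **SNP QC** — MAF < 0.01, locus missingness > 25%, parental
   Hardy–Weinberg deviation (p < 1e-06), sample missingness > 25%; nested
   MAF-threshold marker panels.
3. **Parentage** — trio Mendelian-exclusion search over all candidate
   sire×dam pairs with a genotyping-error tolerance (compiled scan).
4. **Relationship matrices** — pedigree numerator matrix A (tabular
   method) and VanRaden method-1 genomic matrix G.
5. **Variance components** — AI-REML under the animal model
   `y = Xb + Zu + e`, `u ~ N(0, K sigma_g2)`, univariate and bivariate
   (`h2 = sigma_g2 / (sigma_g2 + sigma_e2)`), with delta-method standard
   errors.
6. **GWAS** — two-step mixed-model single-marker scan with Bonferroni
   threshold 0.05/N.
7. **Genomic selection** — PBLUP vs GBLUP breeding values from Henderson's
   mixed-model equations, fivefold cross-validation repeated 10 times,
   accuracy `cor(EBV, y)/h` and dispersion bias (slope of y on EBV) across
   marker-density scenarios.

The central fitting function is `animal_model(formula, data, relmat)`,
which returns an S3 object with `print`, `summary`, `coef`, `predict`,
`residuals`, `simulate` and `plot` methods.

## A worked example

```r
library(carpgs)

cfg <- sim_config(n_offspring = 300, n_markers = 1000, n_qtl = 200, seed = 1)
pop <- simulate_population(cfg)

qc <- filter_genotypes(pop$genotypes_obs, pop$founder_ids)
print(qc)
#> SNP quality control
#>   samples: 360 -> 360 (missingness <= 0.25)
#>   loci:    1000 -> 996 (MAF) -> 996 (missingness) -> 992 (HWE)

asg <- assign_parentage(qc$genotypes[pop$offspring_ids, ],
                        qc$genotypes[pop$sire_ids, ],
                        qc$genotypes[pop$dam_ids, ])
print(asg)
#> Parentage assignment: 300 / 300 offspring uniquely assigned (tol 0.040)
#>   150 full-sib families, sizes 1-6 (mean 2.0)

G <- condition_relmat(vanraden_grm(qc$genotypes[pop$offspring_ids, ]))
fit <- animal_model(length_mm ~ cross, pop$phenotypes, G)
summary(fit)
#> Variance components:
#>  component estimate    se
#>   sigma_g2    16.28 5.954
#>   sigma_e2    36.10 4.984
#>
#> Derived genetic parameters:
#>  quantity estimate     se
#>        h2   0.3108 0.1001
#>
#> logLik -731.868, 6 iterations, converged: TRUE

sch <- make_folds(pop$offspring_ids, 5, 10, seed = 1)
cv <- density_scenarios(length_mm ~ cross, pop$phenotypes,
                        qc$genotypes[pop$offspring_ids, ],
                        pedigree = assignment_pedigree(asg),
                        thresholds = c(0.3, 0.45), scheme = sch)
summary(cv)
#>   scenario method n_markers  accuracy         se      bias
#> 1       FD  GBLUP       992 0.5493527 0.04284662 1.2435578
#> 2   maf0.3  GBLUP       395 0.4698703 0.04301118 1.1409888
#> 3  maf0.45  GBLUP        78 0.1601922 0.06753820 0.9455981
#> 4    PBLUP  PBLUP        NA 0.5935546 0.05543045 1.2316214
```

The QC report shows how many loci each filter removed; the parentage
summary counts uniquely assigned offspring and the resulting family-size
distribution; `summary(fit)` gives the REML variance components and the
heritability of standard length with their standard errors (here
h² ≈ 0.31 ± 0.10, consistent with the generating value 0.33); and the CV
table reports, per scenario, the mean prediction accuracy over 5×10
validation folds, its SE over repeats, and the dispersion bias (1 = EBVs
correctly scaled). At this deliberately small demonstration scale (300
offspring, 1,000 markers) accuracies are below — and noisier than — those
of a full-sized run, and the 78-SNP MAF > 0.45 panel carries little
information; the full study-scale behaviour is exercised by the acceptance
script below.

A YAML-driven end-to-end run (simulate → QC → parentage → variance
components → GWAS → CV) is available through `run_pipeline()` or the thin
command-line wrapper in `inst/scripts/carpgs-cli.R`.

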