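# Synthetic-population generator: founders, mating, gene drop, phenotypes,
# genotyping noise.

test_that("founder haplotypes follow the configured MAF law", {
  cfg <- sim_config(n_markers = 400, n_qtl = 0, founder_maf = c(0.5, 0.5),
                    seed = 1)
  gen <- genome_template(400, 0, seed = 1)
  f <- simulate_founders(cfg, gen, seed = 1)
  expect_equal(dim(f$haps), c(120, 400))
  # at p = 0.5 expected heterozygosity is 0.5 per locus
  het <- mean(f$haps[seq(1, 119, 2), ] != f$haps[seq(2, 120, 2), ])
  expect_lt(abs(het - 0.5), 0.01)

  # fraction of loci with realized MAF > 0.3 matches a Monte-Carlo oracle
  # under binomial sampling of 120 alleles with p ~ U(0.01, 0.5)
  cfg2 <- sim_config(n_markers = 2000, n_qtl = 0, seed = 2)
  gen2 <- genome_template(2000, 0, seed = 2)
  f2 <- simulate_founders(cfg2, gen2, seed = 2)
  cnt <- colSums(f2$haps)
  frac <- mean(pmin(cnt, 120 - cnt) / 120 > 0.3)
  set.seed(99)
  p_mc <- runif(2e5, 0.01, 0.5)
  cnt_mc <- rbinom(2e5, 120, p_mc)
  frac_mc <- mean(pmin(cnt_mc, 120 - cnt_mc) / 120 > 0.3)
  expect_lt(abs(frac - frac_mc), 0.04)
})

test_that("partial factorial mating uses every parent and matches the design", {
  cfg <- sim_config(seed = 5)
  ped <- mate_partial_factorial(cfg, seed = 5)
  off <- ped[ped$sire != "0", ]
  expect_equal(nrow(off), 1425)
  expect_equal(length(unique(off$sire)), 40)
  expect_equal(length(unique(off$dam)), 20)
  expect_lte(length(unique(paste(off$sire, off$dam))), 200)
  # sire and dam of each offspring share a block
  sblk <- ped$block[match(off$sire, ped$id)]
  dblk <- ped$block[match(off$dam, ped$id)]
  expect_true(all(sblk == dblk & sblk == off$block))
  # overdispersed family sizes in the study's observed range
  fam <- table(paste(off$sire, off$dam))
  expect_gt(max(fam), 12)
  expect_gt(mean(fam), 6)
  expect_lt(mean(fam), 8.5)

  tiny <- sim_config()
  tiny$n_offspring <- 3L
  expect_error(mate_partial_factorial(tiny), "at least")
})

test_that("family sizes approach uniform as concentration grows", {
  cfg <- sim_config(family_concentration = 1e6, seed = 6)
  ped <- mate_partial_factorial(cfg, seed = 6)
  fam <- table(paste(ped$sire, ped$dam)[ped$sire != "0"])
  expect_gte(length(fam), 198)
  # multinomial with uniform probabilities: SD of sizes ~ sqrt(7) not ~4
  expect_lt(stats::sd(fam), 3.5)
})

test_that("gene drop recombines at the Haldane rate", {
  # two markers 10 cM apart on one pseudo-chromosome; sire heterozygous
  # in coupling, dam fixed, so the offspring dosage reveals the sire gamete
  gen <- structure(list(
    map = data.frame(lg = 1L, length_cm = 10, n_markers = 2L),
    marker_pos = list(c(0, 10)), qtl_pos = list(numeric(0)),
    marker_lg = c(1L, 1L), qtl_lg = integer(0)), class = "genome_template")
  loci <- data.frame(lg = 1L, pos_cm = c(0, 10), type = "marker",
                     name = c("m1", "m2"))
  n_off <- 10000
  ped <- data.frame(id = c("S1", "D1", sprintf("O%d", 1:n_off)),
                    sire = c("0", "0", rep("S1", n_off)),
                    dam = c("0", "0", rep("D1", n_off)))
  founders <- list(haps = rbind(c(1, 1), c(0, 0), c(0, 0), c(0, 0)),
                   loci = loci, freq = c(0.5, 0.5), ids = c("S1", "D1"))
  drop <- gene_drop(ped, founders, gen, seed = 7)
  off <- drop$markers[-(1:2), ]
  r_hat <- mean(off[, 1] != off[, 2])
  r_exp <- (1 - exp(-0.2)) / 2   # 0.0906
  expect_lt(abs(r_hat - r_exp), 4 * sqrt(r_exp * (1 - r_exp) / n_off))

  # zero distance: alleles always co-inherited
  gen0 <- gen; gen0$marker_pos <- list(c(5, 5))
  founders0 <- founders; founders0$loci$pos_cm <- c(5, 5)
  drop0 <- gene_drop(ped[1:1002, ], founders0, gen0, seed = 8)
  off0 <- drop0$markers[-(1:2), ]
  expect_true(all(off0[, 1] == off0[, 2]))
})

test_that("offspring allele frequencies track founder frequencies", {
  pop <- small_pop()
  p_founder <- colMeans(pop$genotypes[pop$founder_ids, ]) / 2
  p_off <- colMeans(pop$genotypes[pop$offspring_ids, ]) / 2
  expect_gt(cor(p_founder, p_off), 0.97)
  expect_lt(mean(abs(p_founder - p_off)), 0.05)
})

test_that("true breeding values regress on mid-parent with slope one", {
  pop <- small_pop()
  ped <- pop$pedigree
  off <- pop$offspring_ids
  u <- pop$true_bv[, 2]
  mp <- (u[ped$sire[match(off, ped$id)]] + u[ped$dam[match(off, ped$id)]]) / 2
  sl <- coef(lm(u[off] ~ mp))[2]
  expect_lt(abs(sl - 1), 0.15)
})

test_that("phenotype model honours the trait targets", {
  cfg <- sim_config()
  # algebraic oracle for the residual correlation
  re_exp <- (0.93 * 4.6 * 7.1 - 0.94 * sqrt(0.26) * 4.6 * sqrt(0.33) * 7.1) /
    (sqrt(0.74) * 4.6 * sqrt(0.67) * 7.1)
  expect_equal(implied_residual_correlation(cfg), re_exp, tolerance = 1e-12)

  pop <- small_pop()
  expect_equal(pop$residual_correlation,
               implied_residual_correlation(pop$config))
  r <- cor(pop$phenotypes$weight_g, pop$phenotypes$length_mm)
  expect_lt(abs(r - 0.93), 0.035)
  # additive variance scaled exactly to h2 * sdP^2 among offspring
  expect_equal(var(pop$true_bv[pop$offspring_ids, 2]),
               0.33 * 7.1^2, tolerance = 1e-8)

  # degenerate case: no heritability, no breeding values
  cfg0 <- sim_config(n_offspring = 100, n_markers = 60, n_qtl = 20,
                     h2_weight = 0, h2_length = 0, seed = 9)
  pop0 <- simulate_population(cfg0)
  expect_true(all(pop0$true_bv == 0))

  # impossible (rp, rg, h2) triple is rejected with an informative error
  expect_error(sim_config(rp_target = 0.95, rg = 0, h2_weight = 0.9,
                          h2_length = 0.9),
               "inconsistent trait targets")
})

test_that("genotyping noise matches its nominal rates and keeps the clean matrix", {
  pop <- small_pop()
  g <- pop$genotypes
  expect_identical(apply_genotyping_noise(g, 0, 0, seed = 1), g)
  obs <- apply_genotyping_noise(g, error_rate = 0, missing_rate = 0.05, seed = 2)
  expect_lt(abs(mean(is.na(obs)) - 0.05), 0.005)
  obs2 <- apply_genotyping_noise(g, error_rate = 0.1, missing_rate = 0, seed = 3)
  expect_lt(abs(mean(obs2 != g) - 0.1), 0.005)
  # erroneous calls are a different valid dosage
  expect_true(all(obs2[obs2 != g] %in% 0:2))
  expect_false(anyNA(obs2))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_offspring = 80, n_markers = 120, n_qtl = 30, seed = 77)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$genotypes_obs, b$genotypes_obs)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$pedigree, b$pedigree)
})

test_that("ancestral burn-in builds linkage disequilibrium", {
  cfg <- sim_config(n_offspring = 60, n_markers = 2500, n_qtl = 0,
                    founder_generations = 25, seed = 13)
  gen <- genome_template(2500, 0, seed = 13)
  f_ld <- simulate_founders(cfg, gen, seed = 13)
  cfg0 <- sim_config(n_offspring = 60, n_markers = 2500, n_qtl = 0,
                     founder_generations = 0, seed = 13)
  f_le <- simulate_founders(cfg0, gen, seed = 13)
  mean_r2 <- function(f) {
    dos <- f$haps[seq(1, nrow(f$haps), 2), ] + f$haps[seq(2, nrow(f$haps), 2), ]
    keep <- which(apply(dos, 2, stats::sd) > 0 & f$loci$lg %in% 1:5)
    pos <- f$loci$pos_cm[keep] + 1000 * f$loci$lg[keep]
    pairs <- which(abs(outer(pos, pos, "-")) < 3 & upper.tri(diag(length(pos))),
                   arr.ind = TRUE)
    mean(cor(dos[, keep])[pairs]^2)
  }
  expect_gt(mean_r2(f_ld), mean_r2(f_le) + 0.05)
})
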