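# Synthetic populations with the mating design, genome and trait
# architecture of the carp juvenile-growth study: 4 factorial blocks of
# 5 dams x 10 sires, ~1,425 offspring, a 50-linkage-group genome, and
# bivariate weight/length phenotypes under an additive polygenic model.

#' Simulation configuration
#'
#' Collects all parameters of the synthetic carp population. Defaults
#' reproduce the study design: four factorial mating blocks of 5 dams x 10
#' sires (60 founders), 1,425 offspring, 12,311 SNP markers on the fixed
#' 50-group map, 2,000 QTL, heritabilities 0.26 (weight) / 0.33 (length),
#' genetic correlation 0.94 and phenotypic correlation 0.93.
#'
#' @param n_blocks Number of factorial mating blocks.
#' @param dams_per_block,sires_per_block Parents per block.
#' @param n_offspring Total offspring across blocks.
#' @param n_markers,n_qtl Marker and QTL counts for [genome_template()].
#' @param founder_maf Range (min, max) of the uniform law for base-population
#'   minor-allele frequencies.
#' @param founder_ne Effective size of the randomly mating ancestral
#'   population the founders are drawn from (>= total founders).
#' @param founder_generations Number of ancestral random-mating generations
#'   simulated before drawing the founders (default 0: founders in exact
#'   linkage equilibrium). Positive values build the short-range linkage
#'   disequilibrium and co-ancestry of a closed hatchery strain, at the cost
#'   of allele-frequency drift and a mis-specified pedigree A (which assumes
#'   unrelated founders).
#' @param h2_weight,h2_length Narrow-sense heritabilities.
#' @param rg Additive genetic correlation between weight and length.
#' @param rp_target Target phenotypic correlation; the residual correlation
#'   is solved from `rp_target`, `rg` and the heritabilities.
#' @param mean_weight,sd_weight Phenotypic mean (g) and SD of weight.
#' @param mean_length,sd_length Phenotypic mean (mm) and SD of standard length.
#' @param block_effect_frac SD of the random cross (block) effect, as a
#'   fraction of the phenotypic SD of each trait.
#' @param genotyping_error_rate Per-genotype probability that an observed
#'   dosage is replaced by a different one.
#' @param missing_rate Per-genotype probability of a missing call.
#' @param family_concentration Dirichlet concentration governing
#'   overdispersion of full-sib family sizes (smaller = more variable).
#' @param seed Integer seed controlling the whole simulation.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_blocks = 4L, dams_per_block = 5L, sires_per_block = 10L,
                       n_offspring = 1425L, n_markers = 12311L, n_qtl = 2000L,
                       founder_maf = c(0.01, 0.5),
                       founder_ne = 60L, founder_generations = 0L,
                       h2_weight = 0.26, h2_length = 0.33,
                       rg = 0.94, rp_target = 0.93,
                       mean_weight = 16.3, sd_weight = 4.6,
                       mean_length = 77, sd_length = 7.1,
                       block_effect_frac = 0.25,
                       genotyping_error_rate = 0.01, missing_rate = 0.05,
                       family_concentration = 5, seed = NULL) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              dams_per_block = as.integer(dams_per_block),
              sires_per_block = as.integer(sires_per_block),
              n_offspring = as.integer(n_offspring),
              n_markers = as.integer(n_markers), n_qtl = as.integer(n_qtl),
              founder_maf = founder_maf,
              founder_ne = as.integer(founder_ne),
              founder_generations = as.integer(founder_generations),
              h2_weight = h2_weight, h2_length = h2_length,
              rg = rg, rp_target = rp_target,
              mean_weight = mean_weight, sd_weight = sd_weight,
              mean_length = mean_length, sd_length = sd_length,
              block_effect_frac = block_effect_frac,
              genotyping_error_rate = genotyping_error_rate,
              missing_rate = missing_rate,
              family_concentration = family_concentration,
              seed = seed)
  stopifnot(cfg$n_blocks >= 1, cfg$dams_per_block >= 1, cfg$sires_per_block >= 1,
            cfg$n_offspring >= cfg$n_blocks)
  if (length(founder_maf) != 2 || founder_maf[1] <= 0 || founder_maf[2] > 0.5 ||
      founder_maf[1] > founder_maf[2])
    stop("founder_maf must be a (min, max) range within (0, 0.5]")
  for (h in c(cfg$h2_weight, cfg$h2_length))
    if (h < 0 || h >= 1) stop("heritabilities must lie in [0, 1)")
  if (abs(cfg$rg) > 1) stop("|rg| must be <= 1")
  for (r in c(cfg$genotyping_error_rate, cfg$missing_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (cfg$family_concentration <= 0) stop("family_concentration must be > 0")
  nf <- cfg$n_blocks * (cfg$dams_per_block + cfg$sires_per_block)
  if (cfg$founder_generations < 0) stop("founder_generations must be >= 0")
  if (cfg$founder_generations > 0 && cfg$founder_ne < nf)
    stop("founder_ne must be at least the number of founders (", nf, ")")
  # fail early if the implied residual correlation is impossible
  implied_residual_correlation(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Residual correlation implied by the trait targets
#'
#' Solves the residual correlation `re` from the identity
#' `rp * sPw * sPl = rg * sgw * sgl + re * sew * sel`, where the genetic and
#' residual SDs follow from the heritabilities and phenotypic SDs.
#'
#' @param cfg A [sim_config()].
#' @return The scalar residual correlation.
#' @export
implied_residual_correlation <- function(cfg) {
  sgw <- sqrt(cfg$h2_weight) * cfg$sd_weight
  sgl <- sqrt(cfg$h2_length) * cfg$sd_length
  sew <- sqrt(1 - cfg$h2_weight) * cfg$sd_weight
  sel <- sqrt(1 - cfg$h2_length) * cfg$sd_length
  if (sew == 0 || sel == 0) return(0)
  re <- (cfg$rp_target * cfg$sd_weight * cfg$sd_length - cfg$rg * sgw * sgl) /
    (sew * sel)
  if (abs(re) > 1)
    stop(sprintf(paste("inconsistent trait targets: rp=%.3f, rg=%.3f,",
                       "h2=(%.2f, %.2f) imply residual correlation %.3f"),
                 cfg$rp_target, cfg$rg, cfg$h2_weight, cfg$h2_length, re))
  re
}

# Founder ids: sires "S001".., dams "D001".., offspring "O0001"..
.founder_ids <- function(cfg) {
  ns <- cfg$n_blocks * cfg$sires_per_block
  nd <- cfg$n_blocks * cfg$dams_per_block
  list(sires = sprintf("S%03d", seq_len(ns)), dams = sprintf("D%03d", seq_len(nd)))
}

#' Simulate founder haplotypes
#'
#' Draws per-locus allele frequencies from the base-population MAF law
#' (uniform on `cfg$founder_maf`) and base haplotypes as independent
#' Bernoulli draws (linkage equilibrium). When `cfg$founder_generations > 0`
#' the base population of size `cfg$founder_ne` is then mated at random for
#' that many generations, building the short-range linkage disequilibrium
#' and low-level co-ancestry characteristic of a closed hatchery strain,
#' and the founders are drawn from the final generation. With
#' `founder_generations = 0` founders are in exact linkage equilibrium.
#' Marker and QTL loci are handled jointly so that gene dropping respects
#' their interleaved map positions.
#'
#' @param cfg A [sim_config()].
#' @param genome A [genome_template()].
#' @param seed Optional seed (omit to continue the current RNG stream).
#' @return A list with `haps` (2 rows per founder, loci in map order),
#'   `loci` (data frame: lg, pos_cm, type, name), `freq` (base-population
#'   allele frequencies) and `ids`.
#' @export
simulate_founders <- function(cfg, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- .genome_loci(genome)
  nf <- cfg$n_blocks * (cfg$dams_per_block + cfg$sires_per_block)
  L <- nrow(loci)
  p <- stats::runif(L, cfg$founder_maf[1], cfg$founder_maf[2])
  lay <- .lg_layout(loci, genome)
  if (cfg$founder_generations > 0) {
    ne <- cfg$founder_ne
    haps <- matrix(stats::rbinom(2L * ne * L, 1L, rep(p, each = 2L * ne)),
                   nrow = 2L * ne, ncol = L)
    for (gen in seq_len(cfg$founder_generations)) {
      nxt <- matrix(0L, 2L * ne, L)
      for (i in seq_len(ne)) {
        par <- sample.int(ne, 2L)   # two distinct random parents
        nxt[2L * i - 1L, ] <- .meiosis(haps[2L * par[1] - 1L, ],
                                       haps[2L * par[1], ],
                                       lay$index, lay$pos, lay$len)
        nxt[2L * i, ] <- .meiosis(haps[2L * par[2] - 1L, ],
                                  haps[2L * par[2], ],
                                  lay$index, lay$pos, lay$len)
      }
      haps <- nxt
    }
    pick <- sample.int(ne, nf)
    haps <- haps[as.vector(rbind(2L * pick - 1L, 2L * pick)), , drop = FALSE]
  } else {
    haps <- matrix(stats::rbinom(2L * nf * L, 1L, rep(p, each = 2L * nf)),
                   nrow = 2L * nf, ncol = L)
  }
  fid <- .founder_ids(cfg)
  list(haps = haps, loci = loci, freq = p, ids = c(fid$sires, fid$dams))
}

# per-linkage-group locus indices, positions and lengths used by .meiosis
.lg_layout <- function(loci, genome) {
  lv <- factor(loci$lg, levels = genome$map$lg)
  list(index = split(seq_len(nrow(loci)), lv),
       pos = split(loci$pos_cm, lv),
       len = genome$map$length_cm)
}

# Interleave marker and QTL loci in map order; returns one row per locus.
.genome_loci <- function(genome) {
  mk <- data.frame(lg = genome$marker_lg, pos_cm = unlist(genome$marker_pos),
                   type = "marker")
  mk$name <- sprintf("LG%d_M%d", mk$lg, stats::ave(seq_len(nrow(mk)), mk$lg,
                                                   FUN = seq_along))
  if (length(genome$qtl_lg)) {
    qt <- data.frame(lg = genome$qtl_lg, pos_cm = unlist(genome$qtl_pos),
                     type = "qtl")
    qt$name <- sprintf("LG%d_Q%d", qt$lg, stats::ave(seq_len(nrow(qt)), qt$lg,
                                                     FUN = seq_along))
    loci <- rbind(mk, qt)
  } else loci <- mk
  loci <- loci[order(loci$lg, loci$pos_cm), ]
  rownames(loci) <- NULL
  loci
}

#' Partial factorial mating
#'
#' Builds the pedigree of a partial factorial cross: within each block every
#' dam can be mated to every sire, and offspring counts over the
#' `dams_per_block * sires_per_block` possible pairs are drawn from a
#' Dirichlet-multinomial with concentration `family_concentration`, giving
#' overdispersed full-sib family sizes. Draws are repeated (up to 1,000
#' times) until every sire and dam contributes at least one offspring.
#'
#' @inheritParams simulate_founders
#' @return A pedigree data frame (id, sire, dam, block) with founder rows
#'   first (`sire = dam = "0"`), then offspring.
#' @export
mate_partial_factorial <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$n_offspring < cfg$n_blocks)
    stop("n_offspring must be at least the number of blocks")
  fid <- .founder_ids(cfg)
  block_of_sire <- rep(seq_len(cfg$n_blocks), each = cfg$sires_per_block)
  block_of_dam <- rep(seq_len(cfg$n_blocks), each = cfg$dams_per_block)
  n_per_block <- .apportion(cfg$n_offspring, rep(1, cfg$n_blocks))
  off <- NULL
  for (b in seq_len(cfg$n_blocks)) {
    sires_b <- fid$sires[block_of_sire == b]
    dams_b <- fid$dams[block_of_dam == b]
    pairs <- expand.grid(sire = sires_b, dam = dams_b,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    K <- nrow(pairs)
    for (try in seq_len(1000L)) {
      w <- stats::rgamma(K, shape = cfg$family_concentration, rate = 1)
      sizes <- as.vector(stats::rmultinom(1L, n_per_block[b], w / sum(w)))
      used_s <- unique(pairs$sire[sizes > 0])
      used_d <- unique(pairs$dam[sizes > 0])
      if (length(used_s) == length(sires_b) && length(used_d) == length(dams_b))
        break
      if (try == 1000L) stop("could not mate all parents; increase n_offspring")
    }
    off_b <- data.frame(sire = rep(pairs$sire, sizes), dam = rep(pairs$dam, sizes),
                        block = b)
    off <- rbind(off, off_b)
  }
  ped <- rbind(
    data.frame(id = fid$sires, sire = "0", dam = "0", block = block_of_sire),
    data.frame(id = fid$dams, sire = "0", dam = "0", block = block_of_dam),
    data.frame(id = sprintf("O%04d", seq_len(nrow(off))),
               sire = off$sire, dam = off$dam, block = off$block)
  )
  rownames(ped) <- NULL
  ped
}

# One meiosis: recombine a parent's two haplotype rows along the genome.
# Crossovers per linkage group are Poisson(length/100) with positions
# uniform (Haldane model, no interference); the starting strand is random.
.meiosis <- function(h1, h2, lg_index, lg_pos, lg_len) {
  gam <- integer(length(h1))
  nlg <- length(lg_len)
  nxo <- stats::rpois(nlg, lg_len / 100)
  start <- stats::runif(nlg) < 0.5
  for (g in seq_len(nlg)) {
    idx <- lg_index[[g]]
    if (nxo[g] == 0L) {
      gam[idx] <- if (start[g]) h1[idx] else h2[idx]
    } else {
      xo <- sort(stats::runif(nxo[g], 0, lg_len[g]))
      seg <- findInterval(lg_pos[[g]], xo)
      from1 <- (seg + !start[g]) %% 2L == 0L
      gam[idx] <- ifelse(from1, h1[idx], h2[idx])
    }
  }
  gam
}

#' Drop genes through a pedigree
#'
#' Produces genotypes for every pedigree individual by simulating meioses
#' along the genome with a Haldane (no-interference) crossover process:
#' crossover counts per linkage group are Poisson with mean length/100,
#' positions uniform. Founders take their simulated haplotypes; offspring
#' haplotypes are recombinants of their parents'. No mutation.
#'
#' @param pedigree Pedigree data frame (id, sire, dam, ...) with parents
#'   listed before their offspring; founders have sire = dam = "0".
#' @param founders Output of [simulate_founders()].
#' @param genome The [genome_template()] used for the founders.
#' @param seed Optional seed.
#' @return A list with integer dosage matrices `markers` (individuals x
#'   marker loci, rownames = ids) and `qtl`, plus `marker_info` and
#'   `qtl_info` data frames (lg, pos_cm, name, founder freq).
#' @export
gene_drop <- function(pedigree, founders, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- founders$loci
  lay <- .lg_layout(loci, genome)
  lg_index <- lay$index
  lg_pos <- lay$pos
  lg_len <- lay$len
  n <- nrow(pedigree)
  L <- nrow(loci)
  hap1 <- matrix(NA_integer_, n, L)
  hap2 <- matrix(NA_integer_, n, L)
  row_of <- stats::setNames(seq_len(n), pedigree$id)
  founder_row <- stats::setNames(seq_along(founders$ids), founders$ids)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == "0" && d == "0") {
      fr <- founder_row[[pedigree$id[i]]]
      if (is.null(fr) || is.na(fr)) stop("founder ", pedigree$id[i], " has no haplotypes")
      hap1[i, ] <- founders$haps[2L * fr - 1L, ]
      hap2[i, ] <- founders$haps[2L * fr, ]
    } else {
      si <- row_of[[s]]; di <- row_of[[d]]
      if (is.null(si) || is.null(di) || si >= i || di >= i)
        stop("pedigree must list parents before offspring (individual ",
             pedigree$id[i], ")")
      hap1[i, ] <- .meiosis(hap1[si, ], hap2[si, ], lg_index, lg_pos, lg_len)
      hap2[i, ] <- .meiosis(hap1[di, ], hap2[di, ], lg_index, lg_pos, lg_len)
    }
  }
  dos <- hap1 + hap2
  rownames(dos) <- pedigree$id
  is_mk <- loci$type == "marker"
  info <- data.frame(lg = loci$lg, pos_cm = loci$pos_cm, name = loci$name,
                     founder_freq = founders$freq)
  markers <- dos[, is_mk, drop = FALSE]
  colnames(markers) <- loci$name[is_mk]
  qtl <- dos[, !is_mk, drop = FALSE]
  if (ncol(qtl)) colnames(qtl) <- loci$name[!is_mk]
  list(markers = markers, qtl = qtl,
       marker_info = info[is_mk, ], qtl_info = info[!is_mk, ])
}

#' Simulate bivariate weight/length phenotypes
#'
#' Builds true breeding values as sums of QTL allele effects drawn
#' bivariate-normal across traits with correlation `rg`, rescaled so the
#' additive variance among offspring equals `h2 * sdP^2` exactly per trait.
#' Residuals are bivariate normal with the residual correlation solved by
#' [implied_residual_correlation()]; a random cross (block) effect with SD
#' `block_effect_frac * sdP` per trait (correlated `rp_target` across
#' traits) is added. Only offspring receive phenotypes; breeding values are
#' returned for every individual with QTL genotypes.
#'
#' @param qtl_geno QTL dosage matrix (individuals x QTL, rownames = ids).
#' @param pedigree Pedigree data frame; offspring are rows with known parents.
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return A list with `phenotypes` (data frame: id, cross, weight_g,
#'   length_mm), `true_bv` (matrix, all individuals x 2) and the residual
#'   correlation `re` used.
#' @export
simulate_phenotypes <- function(qtl_geno, pedigree, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  re <- implied_residual_correlation(cfg)
  q <- ncol(qtl_geno)
  is_off <- pedigree$sire != "0" | pedigree$dam != "0"
  off_ids <- pedigree$id[is_off]
  n_off <- length(off_ids)
  sdP <- c(cfg$sd_weight, cfg$sd_length)
  h2 <- c(cfg$h2_weight, cfg$h2_length)
  if (q > 0 && any(h2 > 0)) {
    C <- chol(matrix(c(1, cfg$rg, cfg$rg, 1), 2))
    eff <- matrix(stats::rnorm(2L * q), q, 2) %*% C
    u <- qtl_geno %*% eff
    u_off <- u[off_ids, , drop = FALSE]
    for (t in 1:2) {
      v <- stats::var(u_off[, t])
      sc <- if (v > 0 && h2[t] > 0) sqrt(h2[t] * sdP[t]^2 / v) else 0
      u[, t] <- (u[, t] - mean(u_off[, t])) * sc
    }
  } else {
    u <- matrix(0, nrow(qtl_geno), 2, dimnames = list(rownames(qtl_geno), NULL))
  }
  colnames(u) <- c("weight_g", "length_mm")
  sdE <- sqrt(1 - h2) * sdP
  Ce <- chol(matrix(c(1, re, re, 1), 2))
  e <- (matrix(stats::rnorm(2L * n_off), n_off, 2) %*% Ce) %*% diag(sdE)
  sdB <- cfg$block_effect_frac * sdP
  Cb <- chol(matrix(c(1, cfg$rp_target, cfg$rp_target, 1), 2))
  bmat <- (matrix(stats::rnorm(2L * cfg$n_blocks), cfg$n_blocks, 2) %*% Cb) %*%
    diag(sdB)
  blk <- pedigree$block[is_off]
  y <- matrix(rep(c(cfg$mean_weight, cfg$mean_length), each = n_off), n_off, 2) +
    bmat[blk, , drop = FALSE] + u[off_ids, , drop = FALSE] + e
  phen <- data.frame(id = off_ids,
                     cross = factor(paste0("B", blk)),
                     weight_g = y[, 1], length_mm = y[, 2])
  list(phenotypes = phen, true_bv = u, re = re)
}

#' Add genotyping error and missingness
#'
#' Independently per genotype: with probability `missing_rate` the call is
#' set missing (`NA`); surviving calls are replaced with probability
#' `error_rate` by one of the two other dosages, chosen uniformly.
#'
#' @param g Integer dosage matrix in \{0, 1, 2, NA\}.
#' @param error_rate,missing_rate Per-genotype probabilities.
#' @param seed Optional seed.
#' @return A matrix of the same shape; the input is not modified.
#' @export
apply_genotyping_noise <- function(g, error_rate, missing_rate, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1, missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- g
  n <- length(out)
  if (missing_rate > 0)
    out[stats::runif(n) < missing_rate] <- NA_integer_
  if (error_rate > 0) {
    hit <- which(!is.na(out) & stats::runif(n) < error_rate)
    if (length(hit))
      out[hit] <- (out[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
  }
  out
}

#' Simulate a complete study population
#'
#' Runs the full generator: genome layout, founder haplotypes, partial
#' factorial mating, gene drop, bivariate phenotypes, and genotyping noise.
#' With the default [sim_config()] this emulates the carp study design.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `carp_sim`: a list with `config`, `genome`,
#'   `pedigree`, `phenotypes`, `true_bv`, `genotypes` (clean marker
#'   dosages, all individuals), `genotypes_obs` (with error/missingness),
#'   `qtl_geno`, `marker_info`, and id vectors `founder_ids`/`offspring_ids`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_offspring = 200, n_markers = 500, n_qtl = 100, seed = 1)
#' pop <- simulate_population(cfg)
#' }
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  genome <- genome_template(cfg$n_markers, cfg$n_qtl, seed = NULL)
  founders <- simulate_founders(cfg, genome)
  ped <- mate_partial_factorial(cfg)
  drop <- gene_drop(ped, founders, genome)
  phe <- simulate_phenotypes(drop$qtl, ped, cfg)
  obs <- apply_genotyping_noise(drop$markers, cfg$genotyping_error_rate,
                                cfg$missing_rate)
  fid <- .founder_ids(cfg)
  structure(list(
    config = cfg, genome = genome, pedigree = ped,
    phenotypes = phe$phenotypes, true_bv = phe$true_bv,
    residual_correlation = phe$re,
    genotypes = drop$markers, genotypes_obs = obs, qtl_geno = drop$qtl,
    marker_info = drop$marker_info,
    founder_ids = c(fid$sires, fid$dams),
    sire_ids = fid$sires, dam_ids = fid$dams,
    offspring_ids = ped$id[ped$sire != "0"]
  ), class = "carp_sim")
}

#' @export
print.carp_sim <- function(x, ...) {
  cat("Simulated carp population\n")
  cat("  founders:", length(x$founder_ids),
      " offspring:", length(x$offspring_ids), "\n")
  cat("  markers:", ncol(x$genotypes), " QTL:", ncol(x$qtl_geno), "\n")
  fam <- interaction(x$pedigree$sire, x$pedigree$dam, drop = TRUE)[
    x$pedigree$sire != "0"]
  cat("  full-sib families:", nlevels(droplevels(fam)), "\n")
  invisible(x)
}
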