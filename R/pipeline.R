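# End-to-end orchestration: simulate or load data, then QC -> parentage ->
# relationship matrices -> variance components -> GWAS -> cross-validation.

#' Pipeline configuration
#'
#' Collects stage parameters for [run_pipeline()]. All defaults follow the
#' study's analysis settings. A configuration can also be loaded from a
#' YAML file with [load_config()].
#'
#' @param sim A [sim_config()] used when no input paths are given.
#' @param genotypes,pedigree,phenotypes Optional input paths (VCF/TSV
#'   genotypes, pedigree CSV, phenotype CSV). When supplied, simulation is
#'   skipped.
#' @param trait Trait analysed by GWAS and cross-validation.
#' @param maf_min,locus_miss_max,hwe_p_min,sample_miss_max QC thresholds.
#' @param tolerance,margin Parentage assignment parameters.
#' @param run_parentage If `FALSE`, the supplied pedigree is used directly.
#' @param panels MAF thresholds for the density scenarios.
#' @param n_folds,n_repeats Cross-validation layout.
#' @param alpha Identity blending weight for G.
#' @param stages Character vector of stages to run, in order.
#' @param seed Global seed propagated to every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), genotypes = NULL,
                            pedigree = NULL, phenotypes = NULL,
                            trait = "length_mm",
                            maf_min = 0.01, locus_miss_max = 0.25,
                            hwe_p_min = 1e-06, sample_miss_max = 0.25,
                            tolerance = 0.04, margin = 0.01,
                            run_parentage = TRUE,
                            panels = c(0.1, 0.2, 0.3, 0.4, 0.45),
                            n_folds = 5L, n_repeats = 10L, alpha = 0.01,
                            stages = c("qc", "parentage", "varcomp", "gwas", "cv"),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file override [pipeline_config()] defaults;
#' a `sim:` block overrides [sim_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim
  y$sim <- NULL
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  cfg <- do.call(pipeline_config, y)
  if (!is.null(simargs)) cfg$sim <- do.call(sim_config, simargs)
  if (is.null(simargs$seed) && !is.null(cfg$seed)) cfg$sim$seed <- cfg$seed
  cfg
}

#' Run the evaluation pipeline
#'
#' Executes the configured stages in order on simulated or supplied data and
#' writes the stage artifacts (QC report, assignment table, variance
#' component JSON, GWAS TSV, CV table) under `out_dir`. Each output carries
#' a provenance header with the package version and seed.
#'
#' @param cfg A [pipeline_config()] or path to a YAML file.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  set.seed(cfg$seed)
  res <- list(config = cfg)

  if (is.null(cfg$genotypes)) {
    say("simulating population (seed ", cfg$seed, ")")
    if (is.null(cfg$sim$seed)) cfg$sim$seed <- cfg$seed
    pop <- simulate_population(cfg$sim)
    g <- pop$genotypes_obs
    phen <- pop$phenotypes
    true_ped <- pop$pedigree
    parents <- pop$founder_ids
    sires <- pop$sire_ids; dams <- pop$dam_ids
    marker_info <- pop$marker_info
    res$population <- pop
  } else {
    for (p in c(cfg$genotypes, cfg$phenotypes))
      if (!file.exists(p)) stop("input not found: ", p)
    g <- read_genotypes(cfg$genotypes)
    phen <- read_phenotypes_csv(cfg$phenotypes)
    true_ped <- if (!is.null(cfg$pedigree)) read_pedigree_csv(cfg$pedigree)
    if (is.null(true_ped)) stop("a pedigree CSV is required with real inputs")
    sires <- unique(true_ped$sire[true_ped$sire != "0"])
    dams <- unique(true_ped$dam[true_ped$dam != "0"])
    parents <- c(sires, dams)
    marker_info <- NULL
  }

  if ("qc" %in% cfg$stages) {
    say("quality control")
    qc <- filter_genotypes(g, parents = intersect(parents, rownames(g)),
                           maf_min = cfg$maf_min,
                           locus_miss_max = cfg$locus_miss_max,
                           hwe_p_min = cfg$hwe_p_min,
                           sample_miss_max = cfg$sample_miss_max)
    g <- qc$genotypes
    utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(qc$counts), file.path(out_dir, "qc_summary.json"),
                         auto_unbox = TRUE)
    res$qc <- qc
    say("  loci kept: ", qc$counts[["loci_kept"]], " / ", qc$counts[["loci_in"]])
  }

  if ("parentage" %in% cfg$stages && cfg$run_parentage) {
    say("parentage assignment")
    off_ids <- setdiff(rownames(g), parents)
    asg <- assign_parentage(g[off_ids, , drop = FALSE],
                            g[intersect(sires, rownames(g)), , drop = FALSE],
                            g[intersect(dams, rownames(g)), , drop = FALSE],
                            tolerance = cfg$tolerance, margin = cfg$margin)
    blocks <- NULL
    if (!is.null(true_ped$block))
      blocks <- stats::setNames(true_ped$block, true_ped$id)
    ped <- assignment_pedigree(asg, block = blocks)
    utils::write.table(asg$assignments, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$parentage <- asg
    say("  assigned: ", asg$summary$n_assigned, " / ", asg$summary$n_offspring)
  } else {
    ped <- true_ped
  }
  res$pedigree <- ped

  # analysis set: phenotyped offspring with an (assigned) pedigree entry
  off <- ped$id[ped$sire != "0"]
  ids <- intersect(intersect(off, phen$id), rownames(g))
  data <- phen[match(ids, phen$id), ]
  form <- stats::as.formula(paste(cfg$trait, "~ cross"))
  G <- condition_relmat(vanraden_grm(g[ids, , drop = FALSE]), alpha = cfg$alpha)

  if ("varcomp" %in% cfg$stages) {
    say("variance components (n = ", length(ids), ")")
    fitG <- animal_model(form, data, G)
    ped_sub <- ped[ped$id %in% c(ids, sires, dams), ]
    A <- pedigree_amat(ped_sub)
    fitA <- animal_model(form, data, A)
    biv <- animal_model(cbind(weight_g, length_mm) ~ cross, data, G)
    vjson <- list(
      genomic = list(sigma_g2 = fitG$fit$sigma_g2, sigma_e2 = fitG$fit$sigma_e2,
                     h2 = fitG$fit$h2, h2_se = fitG$fit$h2_se,
                     logLik = fitG$fit$logLik, iterations = fitG$fit$iterations),
      pedigree = list(sigma_g2 = fitA$fit$sigma_g2, sigma_e2 = fitA$fit$sigma_e2,
                      h2 = fitA$fit$h2, h2_se = fitA$fit$h2_se),
      bivariate = list(h2 = biv$fit$h2, rg = biv$fit$rg, rg_se = biv$fit$rg_se))
    jsonlite::write_json(vjson, file.path(out_dir, "varcomp.json"),
                         auto_unbox = TRUE, digits = NA)
    res$varcomp <- list(genomic = fitG, pedigree = fitA, bivariate = biv)
  }

  if ("gwas" %in% cfg$stages) {
    say("GWAS (", ncol(g), " SNPs)")
    gw <- gwas_scan(form, data, g[ids, , drop = FALSE], G,
                    marker_info = marker_info)
    utils::write.table(gw$table, file.path(out_dir, "gwas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$gwas <- gw
    say("  lambda_GC = ", round(gw$lambda_gc, 3),
        ", hits: ", sum(gw$table$p < gw$threshold, na.rm = TRUE))
  }

  if ("cv" %in% cfg$stages) {
    say("cross-validation (", cfg$n_folds, "-fold x ", cfg$n_repeats, ")")
    scheme <- make_folds(ids, cfg$n_folds, cfg$n_repeats, seed = cfg$seed)
    ped_sub <- ped[ped$id %in% c(ids, sires, dams), ]
    cvt <- density_scenarios(form, data, g[ids, , drop = FALSE],
                             pedigree = ped_sub, thresholds = cfg$panels,
                             scheme = scheme, alpha = cfg$alpha)
    out <- summary(cvt)
    utils::write.table(out, file.path(out_dir, "cv_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cvt$per_repeat, file.path(out_dir, "cv_table.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    res$cv <- cvt
  }

  say("done; artifacts in ", out_dir)
  invisible(res)
}
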