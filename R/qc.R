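# SNP- and sample-level quality control and MAF-threshold marker panels.

#' Minor allele frequency per locus
#'
#' MAF = min(p, 1 - p) with p the counted-allele frequency among non-missing
#' genotypes. Loci with no genotyped individual get `NA`.
#'
#' @param g Dosage matrix (individuals x loci) in \{0, 1, 2, NA\}.
#' @return Named numeric vector of MAFs in \[0, 0.5\].
#' @export
compute_maf <- function(g) {
  if (length(g) == 0) stop("empty genotype matrix")
  n_ok <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_ok)
  p[n_ok == 0] <- NA_real_
  pmin(p, 1 - p)
}

# Per-locus missing fraction.
locus_missingness <- function(g) colMeans(is.na(g))

# Per-sample missing fraction.
sample_missingness <- function(g) rowMeans(is.na(g))

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against Hardy-Weinberg proportions at the observed allele
#' frequency, computed per locus. Monomorphic loci get p = 1; loci with no
#' genotyped individual get `NA`.
#'
#' @param g Dosage matrix (typically parents only) in \{0, 1, 2, NA\}.
#' @return Named numeric vector of p-values.
#' @export
hwe_test <- function(g) {
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  chi2 <- ifelse(p == 0 | p == 1, 0,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  pv <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  pv[n == 0] <- NA_real_
  stats::setNames(pv, colnames(g))
}

#' Apply the study's quality-control filters
#'
#' Filters samples first (missing fraction > `sample_miss_max` dropped),
#' then loci in a fixed, recorded order: MAF < `maf_min`, locus missingness
#' > `locus_miss_max`, and Hardy-Weinberg deviation in the parental samples
#' (p < `hwe_p_min`). MAF is computed on all genotyped animals; the HWE test
#' uses parents only.
#'
#' @param g Dosage matrix with rownames = individual ids.
#' @param parents Character vector of parental ids (rows of `g`).
#' @param maf_min,locus_miss_max,hwe_p_min,sample_miss_max Filter thresholds.
#' @return A list of class `qc_result`: `genotypes` (filtered matrix),
#'   `report` (per-locus data frame with maf, missingness, HWE p, pass flag
#'   and reason), `samples` (per-sample missingness and pass flag) and
#'   `counts` (records surviving each step).
#' @export
filter_genotypes <- function(g, parents, maf_min = 0.01, locus_miss_max = 0.25,
                             hwe_p_min = 1e-06, sample_miss_max = 0.25) {
  for (th in c(maf_min, locus_miss_max, sample_miss_max))
    if (th < 0 || th > 1) stop("thresholds must lie in [0, 1]")
  if (hwe_p_min < 0 || hwe_p_min > 1) stop("hwe_p_min must lie in [0, 1]")
  if (!all(parents %in% rownames(g)))
    stop("some parent ids are absent from the genotype matrix")
  smiss <- sample_missingness(g)
  keep_s <- smiss <= sample_miss_max
  samples <- data.frame(id = rownames(g), missing = smiss, pass = keep_s)
  g1 <- g[keep_s, , drop = FALSE]
  parents1 <- intersect(parents, rownames(g1))
  maf <- compute_maf(g1)
  lmiss <- locus_missingness(g1)
  hwe <- hwe_test(g1[parents1, , drop = FALSE])
  reason <- rep("", ncol(g1))
  fail_maf <- is.na(maf) | maf < maf_min
  fail_miss <- lmiss > locus_miss_max
  fail_hwe <- !is.na(hwe) & hwe < hwe_p_min
  reason[fail_hwe] <- "hwe"
  reason[fail_miss] <- "missingness"
  reason[fail_maf] <- "maf"      # first filter in order wins the label
  pass <- !(fail_maf | fail_miss | fail_hwe)
  report <- data.frame(locus = colnames(g1), maf = maf, missing = lmiss,
                       hwe_p = hwe, pass = pass, reason = reason,
                       row.names = NULL)
  counts <- c(samples_in = nrow(g), samples_kept = sum(keep_s),
              loci_in = ncol(g1),
              loci_after_maf = sum(!fail_maf),
              loci_after_missing = sum(!fail_maf & !fail_miss),
              loci_kept = sum(pass))
  structure(list(genotypes = g1[, pass, drop = FALSE], report = report,
                 samples = samples, counts = counts,
                 thresholds = c(maf_min = maf_min, locus_miss_max = locus_miss_max,
                                hwe_p_min = hwe_p_min,
                                sample_miss_max = sample_miss_max)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("SNP quality control\n")
  cat(sprintf("  samples: %d -> %d (missingness <= %.2f)\n",
              x$counts[["samples_in"]], x$counts[["samples_kept"]],
              x$thresholds[["sample_miss_max"]]))
  cat(sprintf("  loci:    %d -> %d (MAF) -> %d (missingness) -> %d (HWE)\n",
              x$counts[["loci_in"]], x$counts[["loci_after_maf"]],
              x$counts[["loci_after_missing"]], x$counts[["loci_kept"]]))
  invisible(x)
}

#' Nested MAF-threshold marker panels
#'
#' One panel per threshold, containing the loci with MAF strictly above it
#' (so a "minimum MAF of 0.45" panel is `maf > 0.45`). Panels are nested:
#' higher thresholds give subsets of lower ones.
#'
#' @param g Dosage matrix.
#' @param thresholds Numeric vector of MAF thresholds in \[0, 0.5).
#' @return Named list of character vectors of locus names, one per threshold.
#' @export
maf_threshold_panels <- function(g, thresholds) {
  if (any(thresholds < 0 | thresholds >= 0.5))
    stop("thresholds must lie in [0, 0.5)")
  maf <- compute_maf(g)
  out <- lapply(thresholds, function(th)
    colnames(g)[!is.na(maf) & maf > th])
  names(out) <- sprintf("maf%g", thresholds)
  out
}
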