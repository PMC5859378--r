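# Single-marker mixed-model association with relationship control.

#' Bonferroni genome-wide threshold
#'
#' @param n_tested Number of tested SNPs (>= 1).
#' @param alpha Family-wise error rate.
#' @return The per-test p-value threshold `alpha / n_tested`.
#' @export
bonferroni_threshold <- function(n_tested, alpha = 0.05) {
  if (n_tested < 1) stop("n_tested must be >= 1")
  alpha / n_tested
}

#' Mixed-model association scan
#'
#' Two-step (EMMAX-style) single-marker GWAS: variance components are
#' estimated once by AI-REML under the null animal model, then each SNP is
#' added as a fixed effect and Wald-tested by generalized least squares with
#' the covariance structure held fixed. The eigendecomposition of the
#' relationship matrix makes the per-SNP step a set of vectorized weighted
#' regressions. Missing dosages are mean-imputed per SNP; monomorphic SNPs
#' get an undefined statistic and are flagged.
#'
#' @param formula Null-model formula, e.g. `length_mm ~ cross`.
#' @param data Data frame with an `id` column.
#' @param genotypes Dosage matrix (individuals x SNPs) covering the
#'   phenotyped ids.
#' @param relmat Relationship matrix for the polygenic term (typically a
#'   conditioned [vanraden_grm()]).
#' @param marker_info Optional data frame with columns `name`, `lg`,
#'   `pos_cm` used to annotate the output.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @return Object of class `gwas_result`: per-SNP table (snp, lg, pos_cm,
#'   maf, beta, se, chi2, p), the genome-wide `threshold`, the genomic
#'   inflation factor `lambda_gc`, and the null-model fit.
#' @export
gwas_scan <- function(formula, data, genotypes, relmat, marker_info = NULL,
                      alpha = 0.05) {
  null_fit <- animal_model(formula, data, relmat)
  if (null_fit$bivariate) stop("gwas_scan is univariate; pass one trait")
  ids <- null_fit$ids
  g <- genotypes[ids, , drop = FALSE]
  maf <- compute_maf(g)
  f <- null_fit$fit
  w <- 1 / (f$sigma_g2 * f$d + f$sigma_e2)
  mf <- stats::model.frame(formula, data = data[match(ids, data$id), ])
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- drop(stats::model.response(mf))
  Xt <- crossprod(f$U, X)
  yt <- drop(crossprod(f$U, y))
  # mean-impute missing dosages, rotate the SNP matrix once
  p_hat <- colSums(g, na.rm = TRUE) / (2 * pmax(colSums(!is.na(g)), 1L))
  if (anyNA(g)) {
    idx <- which(is.na(g))
    g[idx] <- (2 * p_hat)[((idx - 1L) %/% nrow(g)) + 1L]
  }
  Gt <- crossprod(f$U, g)
  # residualize phenotype and SNPs on the null covariates under weights w
  XtWX <- crossprod(Xt, Xt * w)
  by <- solve(XtWX, crossprod(Xt, w * yt))
  yr <- yt - drop(Xt %*% by)
  Cg <- solve(XtWX, crossprod(Xt, w * Gt))
  Gr <- Gt - Xt %*% Cg
  den <- colSums(Gr * (w * Gr))
  num <- colSums(Gr * (w * yr))
  beta <- num / den
  se <- sqrt(1 / den)
  chi2 <- beta^2 * den
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  mono <- is.na(maf) | maf == 0 | den <= .Machine$double.eps * length(ids)
  beta[mono] <- se[mono] <- chi2[mono] <- pval[mono] <- NA_real_
  tab <- data.frame(snp = colnames(g), maf = maf, beta = beta, se = se,
                    chi2 = chi2, p = pval, row.names = NULL)
  if (!is.null(marker_info)) {
    m <- match(tab$snp, marker_info$name)
    tab$lg <- marker_info$lg[m]
    tab$pos_cm <- marker_info$pos_cm[m]
    tab <- tab[, c("snp", "lg", "pos_cm", "maf", "beta", "se", "chi2", "p")]
  }
  n_tested <- sum(!mono)
  structure(list(table = tab, threshold = bonferroni_threshold(n_tested, alpha),
                 n_tested = n_tested,
                 lambda_gc = stats::median(chi2, na.rm = TRUE) /
                   stats::qchisq(0.5, df = 1),
                 null_fit = null_fit),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("Mixed-model GWAS: %d SNPs tested, threshold %.3g, lambda_GC %.3f\n",
              x$n_tested, x$threshold, x$lambda_gc))
  hits <- sum(x$table$p < x$threshold, na.rm = TRUE)
  cat(sprintf("  genome-wide significant SNPs: %d\n", hits))
  if (hits > 0) {
    top <- x$table[order(x$table$p), ][seq_len(min(hits, 5)), ]
    print(top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Manhattan plot of a GWAS result
#'
#' @param x A [gwas_scan()] result with linkage-group annotation.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gwas_result <- function(x, ...) {
  tab <- x$table
  if (is.null(tab$lg)) stop("no linkage-group annotation; pass marker_info to gwas_scan")
  off <- c(0, cumsum(tapply(tab$pos_cm, tab$lg, max)))
  pos <- tab$pos_cm + off[tab$lg]
  graphics::plot(pos, -log10(tab$p), pch = 20, cex = 0.4,
                 col = 1 + tab$lg %% 2,
                 xlab = "genome position (cM)", ylab = "-log10 p", ...)
  graphics::abline(h = -log10(x$threshold), col = 2, lty = 2)
  invisible(x)
}
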