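# Repeated fivefold cross-validation of PBLUP/GBLUP prediction accuracy
# and bias, with marker-density (MAF-threshold) scenarios sharing folds.

#' Build repeated cross-validation folds
#'
#' Each repeat randomly permutes the individuals and cuts the first
#' `n_folds * floor(n / n_folds)` of them into contiguous validation blocks
#' of equal size; the remainder individuals (n mod n_folds) are never
#' validated, i.e. they join every training set. For 1,214 individuals and
#' five folds this yields validation sets of exactly 242 and training sets
#' of 972.
#'
#' @param ids Character vector of individual ids.
#' @param n_folds,n_repeats Folds per repeat and number of repeats.
#' @param seed Optional seed; memberships are reproducible given the seed.
#' @return An object of class `cv_scheme`: list of repeats, each a list of
#'   validation id vectors.
#' @export
make_folds <- function(ids, n_folds = 5L, n_repeats = 10L, seed = NULL) {
  n <- length(ids)
  if (n < n_folds) stop("fewer individuals than folds")
  if (!is.null(seed)) set.seed(seed)
  nv <- n %/% n_folds
  reps <- lapply(seq_len(n_repeats), function(r) {
    perm <- sample(ids)
    lapply(seq_len(n_folds), function(k) perm[((k - 1L) * nv + 1L):(k * nv)])
  })
  structure(list(folds = reps, n_folds = n_folds, n_repeats = n_repeats,
                 ids = ids, n_validation = nv),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("CV scheme: %d-fold x %d repeats over %d individuals (%d per validation set)\n",
              x$n_folds, x$n_repeats, length(x$ids), x$n_validation))
  invisible(x)
}

#' Cross-validated BLUP accuracy and bias
#'
#' For every repeat and fold: variance components are estimated by AI-REML
#' on the training records (or fixed components are used), Henderson's MME
#' are solved with training phenotypes, and validation animals receive
#' breeding values through the relationship matrix. Accuracy is
#' `cor(EBV, y) / h` over the validation set, with `h` the square root of
#' the heritability from the same source as the components; bias is the
#' ordinary-least-squares slope of phenotype on EBV.
#'
#' @param formula Univariate model formula, e.g. `length_mm ~ cross`.
#' @param data Data frame with an `id` column.
#' @param relmat Relationship matrix covering all ids in the scheme.
#' @param scheme A [make_folds()] scheme over phenotyped individuals.
#' @param components `"per_fold"` (default: REML on each training set) or a
#'   list with `sigma_g2` and `sigma_e2` fixed for all folds.
#' @param h2_accuracy Heritability used in the accuracy denominator `h`:
#'   `NULL` (default) takes it from the same source as the components
#'   (per-fold REML or the fixed components); a numeric value fixes one
#'   common `h` — required when accuracies are compared across relationship
#'   matrices, since each matrix scales its own heritability differently.
#' @return Object of class `cv_result`: per-fold data frame and summary
#'   (mean accuracy, SE over repeat means, mean bias).
#' @export
cv_blup <- function(formula, data, relmat, scheme, components = "per_fold",
                    h2_accuracy = NULL) {
  stopifnot(inherits(scheme, "cv_scheme"))
  data <- data[match(scheme$ids, data$id), ]
  if (anyNA(data$id)) stop("scheme ids missing from data")
  if (!all(scheme$ids %in% rownames(relmat)))
    stop("scheme ids missing from the relationship matrix")
  mf <- stats::model.frame(formula, data = data)
  y <- drop(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  names(y) <- data$id
  rownames(X) <- data$id
  Kinv <- chol2inv(chol(relmat[scheme$ids, scheme$ids]))
  K <- relmat[scheme$ids, scheme$ids]
  fixed <- is.list(components)
  rows <- list()
  for (r in seq_len(scheme$n_repeats)) {
    for (k in seq_len(scheme$n_folds)) {
      val <- scheme$folds[[r]][[k]]
      trn <- setdiff(scheme$ids, val)
      if (fixed) {
        sg <- components$sigma_g2; se2 <- components$sigma_e2
        h2 <- sg / (sg + se2)
      } else {
        fit <- .reml_uni(y[trn], X[trn, , drop = FALSE], K[trn, trn])
        sg <- fit$sigma_g2; se2 <- fit$sigma_e2; h2 <- fit$h2
      }
      sol <- solve_mme(y[trn], X[trn, , drop = FALSE], trn, K,
                       sigma_g2 = sg, sigma_e2 = se2, Kinv = Kinv)
      u_val <- sol$u[val]
      y_val <- y[val]
      h2_acc <- if (is.null(h2_accuracy)) h2 else h2_accuracy
      if (stats::sd(u_val) == 0 || h2_acc <= 0) {
        acc <- NA_real_; bias <- NA_real_
      } else {
        acc <- stats::cor(u_val, y_val) / sqrt(h2_acc)
        bias <- stats::cov(y_val, u_val) / stats::var(u_val)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = k, n_train = length(trn), n_val = length(val),
        sigma_g2 = sg, sigma_e2 = se2, h2 = h2, accuracy = acc, bias = bias)
    }
  }
  folds <- do.call(rbind, rows)
  rep_means <- tapply(folds$accuracy, folds$rep, mean, na.rm = TRUE)
  summary <- list(
    mean_accuracy = mean(folds$accuracy, na.rm = TRUE),
    se_accuracy = stats::sd(rep_means),
    mean_bias = mean(folds$bias, na.rm = TRUE),
    repeat_accuracy = as.numeric(rep_means),
    repeat_bias = as.numeric(tapply(folds$bias, folds$rep, mean, na.rm = TRUE)),
    mean_h2 = mean(folds$h2))
  structure(list(folds = folds, summary = summary,
                 h2_accuracy = h2_accuracy,
                 components = if (fixed) "fixed" else "per_fold"),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cross-validation: accuracy %.3f (SE %.3f), bias %.3f [h2 %.3f, %s components]\n",
              s$mean_accuracy, s$se_accuracy, s$mean_bias, s$mean_h2,
              x$components))
  invisible(x)
}

#' Marker-density scenarios plus the pedigree baseline
#'
#' Runs [cv_blup()] with identical fold memberships (paired comparison) for
#' the full marker panel, one reduced panel per MAF threshold (loci with MAF
#' strictly above the threshold), and pedigree BLUP. GBLUP scenarios use a
#' VanRaden G conditioned by [condition_relmat()].
#'
#' @param formula,data,scheme As in [cv_blup()].
#' @param genotypes Dosage matrix over (at least) the scheme individuals.
#' @param pedigree Pedigree data frame for the PBLUP baseline; `NULL` skips it.
#' @param thresholds MAF thresholds (default the study's 0.1 ... 0.45).
#' @param alpha Identity blending weight for G.
#' @param h2_accuracy Heritability for the accuracy denominator, shared by
#'   every scenario so that accuracies are comparable across marker panels
#'   and methods: `"full_data"` (default) estimates it once by REML on the
#'   full data with the full-density G; a numeric value fixes it; `NULL`
#'   falls back to each scenario's own per-fold estimates.
#' @return Object of class `cv_table`: named list of `cv_result` objects
#'   (`FD`, `maf0.1`, ..., `PBLUP`) plus a per-repeat accuracy/bias table.
#' @export
density_scenarios <- function(formula, data, genotypes, pedigree = NULL,
                              thresholds = c(0.1, 0.2, 0.3, 0.4, 0.45),
                              scheme, alpha = 0.01, h2_accuracy = "full_data") {
  g <- genotypes[rownames(genotypes) %in% scheme$ids, , drop = FALSE]
  panels <- c(list(FD = colnames(g)),
              if (length(thresholds)) maf_threshold_panels(g, thresholds))
  results <- list()
  meta <- list()
  h2_full <- NULL
  for (nm in names(panels)) {
    loci <- panels[[nm]]
    if (length(loci) == 0) {
      warning("panel ", nm, " is empty; scenario skipped")
      next
    }
    G <- condition_relmat(vanraden_grm(g[, loci, drop = FALSE]), alpha = alpha)
    if (identical(h2_accuracy, "full_data") && is.null(h2_full)) {
      h2_full <- animal_model(formula, data[match(scheme$ids, data$id), ],
                              G)$fit$h2
    }
    h2a <- if (is.numeric(h2_accuracy)) h2_accuracy else h2_full
    results[[nm]] <- cv_blup(formula, data, G, scheme, h2_accuracy = h2a)
    meta[[nm]] <- data.frame(scenario = nm, method = "GBLUP",
                             n_markers = length(loci))
  }
  if (!is.null(pedigree)) {
    A <- pedigree_amat(pedigree)
    h2a <- if (is.numeric(h2_accuracy)) h2_accuracy else h2_full
    results[["PBLUP"]] <- cv_blup(formula, data, A, scheme, h2_accuracy = h2a)
    meta[["PBLUP"]] <- data.frame(scenario = "PBLUP", method = "PBLUP",
                                  n_markers = NA_integer_)
  }
  per_rep <- do.call(cbind, lapply(results, function(r)
    sprintf("%.2f (%.2f)", r$summary$repeat_accuracy, r$summary$repeat_bias)))
  rownames(per_rep) <- paste0("rep", seq_len(scheme$n_repeats))
  structure(list(results = results, scenarios = do.call(rbind, meta),
                 per_repeat = per_rep,
                 h2_accuracy = if (is.numeric(h2_accuracy)) h2_accuracy
                               else h2_full),
            class = "cv_table")
}

#' @export
print.cv_table <- function(x, ...) {
  cat("Prediction accuracy (bias) per repeat:\n")
  print(x$per_repeat, quote = FALSE)
  cat("\nScenario means:\n")
  means <- vapply(x$results, function(r) r$summary$mean_accuracy, 0)
  ses <- vapply(x$results, function(r) r$summary$se_accuracy, 0)
  bias <- vapply(x$results, function(r) r$summary$mean_bias, 0)
  tab <- data.frame(scenario = names(x$results),
                    n_markers = x$scenarios$n_markers,
                    accuracy = round(means, 3), se = round(ses, 3),
                    bias = round(bias, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cv_table <- function(object, ...) {
  data.frame(scenario = names(object$results),
             method = object$scenarios$method,
             n_markers = object$scenarios$n_markers,
             accuracy = vapply(object$results, function(r) r$summary$mean_accuracy, 0),
             se = vapply(object$results, function(r) r$summary$se_accuracy, 0),
             bias = vapply(object$results, function(r) r$summary$mean_bias, 0),
             row.names = NULL)
}
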