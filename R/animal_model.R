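# The user-facing animal-model fit: formula interface, S3 methods.

#' Fit an animal model by AI-REML
#'
#' Fits `y = Xb + u + e` with `u ~ N(0, K sigma_g2)` and
#' `e ~ N(0, I sigma_e2)`, where `K` is a pedigree (A) or genomic (G)
#' relationship matrix, by average-information REML with an EM fallback.
#' A two-column response (`cbind(weight_g, length_mm) ~ cross`) fits the
#' bivariate model with 2x2 genetic and residual covariance matrices and
#' reports the genetic correlation.
#'
#' @param formula Model formula; the left side is one trait or
#'   `cbind(trait1, trait2)`, the right side the fixed effects (e.g. the
#'   cross factor).
#' @param data Data frame with an `id` column matching `relmat` dimnames.
#' @param relmat Relationship matrix ([pedigree_amat()] or [vanraden_grm()],
#'   possibly conditioned). May contain individuals without phenotypes;
#'   breeding values are predicted for all of them.
#' @param tol Convergence tolerance on the relative parameter change.
#' @param max_iter Maximum AI-REML iterations.
#' @return An object of class `animal_model` with variance components,
#'   standard errors, heritability, genetic correlation (bivariate),
#'   fixed-effect estimates, breeding values (`ebv()`) for every individual
#'   in `relmat`, and the REML log-likelihood.
#' @seealso [solve_mme()] for BLUP at fixed variance components.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_offspring = 150, n_markers = 300, n_qtl = 50, seed = 3)
#' pop <- simulate_population(cfg)
#' A <- pedigree_amat(pop$pedigree)
#' fit <- animal_model(length_mm ~ cross, data = pop$phenotypes, relmat = A)
#' summary(fit)
#' }
#' @export
animal_model <- function(formula, data, relmat, tol = 1e-8, max_iter = 100L) {
  if (!"id" %in% names(data)) stop("`data` must contain an `id` column")
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  keep <- rownames(data) %in% rownames(mf)
  ids <- as.character(data$id[keep])
  if (!all(ids %in% rownames(relmat)))
    stop("some phenotyped individuals are missing from the relationship matrix")
  Y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  K <- relmat[ids, ids]
  bivariate <- is.matrix(Y) && ncol(Y) == 2
  fit <- if (bivariate) .reml_biv(Y, X, K, tol = tol, max_iter = max_iter)
         else .reml_uni(drop(Y), X, K, tol = tol, max_iter = max_iter)

  # BLUP of breeding values for every individual in relmat:
  # u_hat = Cov(u_all, y) V^{-1} (y - X beta), with V^{-1} via the rotation
  Kxp <- relmat[, ids, drop = FALSE]
  p <- ncol(X)
  if (bivariate) {
    xb <- cbind(drop(X %*% fit$beta[seq_len(p)]),
                drop(X %*% fit$beta[p + seq_len(p)]))
    R <- Y - xb
    Rt <- crossprod(fit$U, R)
    v11 <- fit$G0[1, 1] * fit$d + fit$R0[1, 1]
    v12 <- fit$G0[1, 2] * fit$d + fit$R0[1, 2]
    v22 <- fit$G0[2, 2] * fit$d + fit$R0[2, 2]
    det <- v11 * v22 - v12^2
    p1 <- (v22 * Rt[, 1] - v12 * Rt[, 2]) / det
    p2 <- (v11 * Rt[, 2] - v12 * Rt[, 1]) / det
    ebv <- (Kxp %*% (fit$U %*% cbind(p1, p2))) %*% fit$G0
    colnames(ebv) <- colnames(Y)
  } else {
    xb <- drop(X %*% fit$beta)
    R <- drop(Y) - xb
    vr <- fit$U %*% ((1 / (fit$sigma_g2 * fit$d + fit$sigma_e2)) *
                       crossprod(fit$U, R))
    ebv <- fit$sigma_g2 * (Kxp %*% vr)
    colnames(ebv) <- "ebv"
  }
  rownames(ebv) <- rownames(relmat)
  u_phen <- ebv[ids, , drop = FALSE]
  resid <- (if (bivariate) R else cbind(R)) - u_phen

  out <- list(call = match.call(), formula = formula, bivariate = bivariate,
              ids = ids,
              traits = if (bivariate) colnames(Y) else deparse(formula[[2]]),
              n = length(ids), fit = fit, ebv = ebv,
              y = if (bivariate) Y else cbind(drop(Y)),
              xb = if (bivariate) xb else cbind(xb),
              resid = resid,
              relmat_kind = attr(relmat, "kind"))
  class(out) <- "animal_model"
  out
}

#' @export
print.animal_model <- function(x, ...) {
  f <- x$fit
  cat("Animal model (AI-REML", if (x$bivariate) ", bivariate" else "", ")\n",
      sep = "")
  cat("  records:", x$n, " relationship:",
      if (is.null(x$relmat_kind)) "custom" else x$relmat_kind, "\n")
  if (x$bivariate) {
    cat(sprintf("  h2 = %.3f (%s), %.3f (%s)\n", f$h2[1], x$traits[1],
                f$h2[2], x$traits[2]))
    cat(sprintf("  genetic correlation = %.3f (SE %.3f)\n", f$rg, f$rg_se))
  } else {
    cat(sprintf("  sigma_g2 = %.4g, sigma_e2 = %.4g\n", f$sigma_g2, f$sigma_e2))
    cat(sprintf("  h2 = %.3f (SE %s)\n", f$h2,
                if (is.na(f$h2_se)) "NA" else sprintf("%.3f", f$h2_se)))
  }
  cat(sprintf("  logLik = %.3f after %d iterations (%s)\n", f$logLik,
              f$iterations, if (f$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  f <- object$fit
  if (object$bivariate) {
    vc <- data.frame(
      component = c("G0[1,1]", "G0[1,2]", "G0[2,2]",
                    "R0[1,1]", "R0[1,2]", "R0[2,2]"),
      estimate = c(f$G0[1, 1], f$G0[1, 2], f$G0[2, 2],
                   f$R0[1, 1], f$R0[1, 2], f$R0[2, 2]),
      se = f$se)
    extra <- data.frame(quantity = c(paste0("h2_", object$traits), "r_g"),
                        estimate = c(f$h2, f$rg), se = c(f$h2_se, f$rg_se))
  } else {
    vc <- data.frame(component = c("sigma_g2", "sigma_e2"),
                     estimate = c(f$sigma_g2, f$sigma_e2), se = f$se)
    extra <- data.frame(quantity = "h2", estimate = f$h2, se = f$h2_se)
  }
  out <- list(varcomp = vc, derived = extra, logLik = f$logLik,
              iterations = f$iterations, converged = f$converged,
              call = object$call)
  class(out) <- "summary.animal_model"
  out
}

#' @export
print.summary.animal_model <- function(x, ...) {
  cat("Variance components:\n")
  print(x$varcomp, row.names = FALSE, digits = 4)
  cat("\nDerived genetic parameters:\n")
  print(x$derived, row.names = FALSE, digits = 4)
  cat(sprintf("\nlogLik %.3f, %d iterations, converged: %s\n",
              x$logLik, x$iterations, x$converged))
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) object$fit$beta

#' @export
logLik.animal_model <- function(object, ...) {
  structure(object$fit$logLik, df = if (object$bivariate) 6 else 2,
            class = "logLik")
}

#' Extract breeding values
#'
#' @param object An [animal_model()] fit.
#' @param ... Unused.
#' @return Matrix of BLUP breeding values, one row per individual in the
#'   relationship matrix the model was fitted with.
#' @export
ebv <- function(object, ...) UseMethod("ebv")

#' @rdname ebv
#' @export
ebv.animal_model <- function(object, ...) object$ebv

#' @export
predict.animal_model <- function(object, ids = NULL, ...) {
  if (is.null(ids)) return(object$ebv)
  object$ebv[ids, , drop = FALSE]
}

#' @export
fitted.animal_model <- function(object, ...) {
  object$xb + object$ebv[object$ids, , drop = FALSE]
}

#' @export
residuals.animal_model <- function(object, ...) object$resid

#' @export
simulate.animal_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- object$fit
  n <- object$n
  out <- vector("list", nsim)
  if (object$bivariate) {
    for (s in seq_len(nsim)) {
      v11 <- f$G0[1, 1] * f$d + f$R0[1, 1]
      v12 <- f$G0[1, 2] * f$d + f$R0[1, 2]
      v22 <- f$G0[2, 2] * f$d + f$R0[2, 2]
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      # per-block Cholesky of the 2x2 rotated covariance
      l11 <- sqrt(v11); l21 <- v12 / l11
      l22 <- sqrt(pmax(v22 - l21^2, 0))
      e1 <- l11 * z1
      e2 <- l21 * z1 + l22 * z2
      out[[s]] <- object$xb + f$U %*% cbind(e1, e2)
    }
  } else {
    sd_rot <- sqrt(f$sigma_g2 * f$d + f$sigma_e2)
    for (s in seq_len(nsim))
      out[[s]] <- object$xb + f$U %*% (sd_rot * stats::rnorm(n))
  }
  out
}

#' @export
plot.animal_model <- function(x, trait = 1, ...) {
  u <- x$ebv[x$ids, trait]
  y <- x$y[, trait]
  graphics::plot(u, y, xlab = "estimated breeding value",
                 ylab = "phenotype",
                 main = if (x$bivariate) x$traits[trait] else x$traits, ...)
  graphics::abline(stats::lm(y ~ u), col = 2)
  invisible(x)
}

#' Heritability of a fitted animal model
#'
#' @param object An [animal_model()] fit.
#' @return Named numeric vector of heritabilities (one per trait).
#' @export
heritability <- function(object) {
  stats::setNames(object$fit$h2,
                  if (object$bivariate) object$traits else object$traits)
}
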