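# Henderson's mixed-model equations at fixed variance components.

#' Solve the mixed-model equations
#'
#' Builds and solves Henderson's MME for `y = Xb + Zu + e` with
#' `u ~ N(0, K sigma_g2)`, `e ~ N(0, I sigma_e2)`:
#' ```
#' | X'X        X'Z          | | b |   | X'y |
#' | Z'X   Z'Z + lambda K^-1 | | u | = | Z'y |
#' ```
#' with `lambda = sigma_e2 / sigma_g2`. Individuals present in `relmat` but
#' without records receive breeding values through their relationship ties
#' (the machinery of BLUP prediction for validation animals).
#'
#' @param y Numeric vector of phenotypes (training records).
#' @param X Fixed-effect design matrix for the records.
#' @param ids Character vector: the individual providing each record; all
#'   must appear in `rownames(relmat)`.
#' @param relmat Relationship matrix over all individuals to evaluate
#'   (training and validation); must be invertible.
#' @param sigma_g2,sigma_e2 Variance components (both > 0).
#' @param Kinv Optional precomputed inverse of `relmat` (it is reused across
#'   cross-validation folds).
#' @return A list with `b` (fixed effects), `u` (named breeding values for
#'   every individual in `relmat`) and `lambda`.
#' @export
solve_mme <- function(y, X, ids, relmat, sigma_g2, sigma_e2, Kinv = NULL) {
  stopifnot(sigma_g2 > 0, sigma_e2 > 0, length(y) == nrow(X),
            length(ids) == length(y))
  all_ids <- rownames(relmat)
  m <- match(ids, all_ids)
  if (anyNA(m)) stop("record individual absent from the relationship matrix")
  n_ind <- length(all_ids)
  p <- ncol(X)
  lambda <- sigma_e2 / sigma_g2
  if (is.null(Kinv)) Kinv <- chol2inv(chol(relmat))
  # Z'Z is diagonal with record counts; Z'X and Z'y are row aggregations
  ZtZ <- tabulate(m, nbins = n_ind)
  ZtX <- matrix(0, n_ind, p)
  Zty <- numeric(n_ind)
  for (k in seq_along(m)) {
    ZtX[m[k], ] <- ZtX[m[k], ] + X[k, ]
    Zty[m[k]] <- Zty[m[k]] + y[k]
  }
  C <- matrix(0, p + n_ind, p + n_ind)
  C[1:p, 1:p] <- crossprod(X)
  C[1:p, p + (1:n_ind)] <- t(ZtX)
  C[p + (1:n_ind), 1:p] <- ZtX
  C[p + (1:n_ind), p + (1:n_ind)] <- lambda * Kinv
  diag(C)[p + (1:n_ind)] <- diag(C)[p + (1:n_ind)] + ZtZ
  rhs <- c(crossprod(X, y), Zty)
  sol <- solve(C, rhs)
  list(b = stats::setNames(sol[1:p], colnames(X)),
       u = stats::setNames(sol[p + (1:n_ind)], all_ids),
       lambda = lambda)
}
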