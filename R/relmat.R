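# Additive relationship matrices: pedigree numerator matrix A (tabular
# method) and VanRaden method-1 genomic relationship matrix G.

#' Pedigree numerator relationship matrix
#'
#' Tabular method: individuals are processed parents-first;
#' `a_ij = (a_{j,sire(i)} + a_{j,dam(i)}) / 2` and
#' `a_ii = 1 + a_{sire(i),dam(i)} / 2`, with unknown parents ("0")
#' contributing zero.
#'
#' @param pedigree Data frame with columns id, sire, dam; founders have
#'   sire = dam = "0". Parents need not precede offspring (rows are sorted
#'   internally); cycles are an error.
#' @return A symmetric matrix of class `relmat` with dimnames = ids and
#'   attribute `kind = "pedigree_A"`.
#' @export
pedigree_amat <- function(pedigree) {
  ped <- pedigree[, c("id", "sire", "dam")]
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  # topological sort: repeatedly emit individuals whose parents are placed
  placed <- character(0)
  rest <- ped
  ord <- NULL
  while (nrow(rest)) {
    ready <- (rest$sire == "0" | rest$sire %in% placed) &
      (rest$dam == "0" | rest$dam %in% placed)
    if (!any(ready)) stop("pedigree contains a cycle or a missing parent id")
    ord <- rbind(ord, rest[ready, ])
    placed <- c(placed, rest$id[ready])
    rest <- rest[!ready, , drop = FALSE]
  }
  n <- nrow(ord)
  A <- matrix(0, n, n, dimnames = list(ord$id, ord$id))
  idx <- stats::setNames(seq_len(n), ord$id)
  pos <- function(p) if (p == "0") 0L else idx[[p]]
  for (i in seq_len(n)) {
    s <- pos(ord$sire[i]); d <- pos(ord$dam[i])
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0) row <- row + A[j, s]
      if (d > 0) row <- row + A[j, d]
      A[j, i] <- A[i, j] <- row / 2
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) A[s, d] / 2 else 0
  }
  A <- A[pedigree$id, pedigree$id]
  structure(A, kind = "pedigree_A", class = c("relmat", "matrix", "array"))
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = Z Z' / (2 * sum(p_j (1 - p_j)))` with `Z = M - 2p`, where `M` is the
#' dosage matrix and `p_j` the counted-allele frequencies. Missing dosages
#' are mean-imputed per locus (replaced by `2 p_j`, i.e. they contribute
#' zero to `Z`); monomorphic loci contribute nothing.
#'
#' @param g Dosage matrix (individuals x loci) in \{0, 1, 2, NA\} with
#'   rownames as ids.
#' @param freqs `"observed"` (default: frequencies computed from `g`) or a
#'   numeric vector of per-locus counted-allele frequencies.
#' @return A symmetric matrix of class `relmat`, attribute `kind =
#'   "genomic_G"`, with the frequencies used stored in attribute `freqs`.
#' @export
vanraden_grm <- function(g, freqs = "observed") {
  if (ncol(g) < 1) stop("no loci in genotype matrix")
  if (identical(freqs, "observed")) {
    n_ok <- colSums(!is.na(g))
    p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_ok, 1L))
  } else {
    p <- freqs
    if (length(p) != ncol(g)) stop("freqs must have one entry per locus")
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all loci are monomorphic: zero VanRaden denominator")
  Z <- sweep(g, 2L, 2 * p)
  Z[is.na(Z)] <- 0        # mean imputation: missing dosage = 2p
  G <- tcrossprod(Z) / denom
  structure(G, kind = "genomic_G", freqs = p,
            class = c("relmat", "matrix", "array"))
}

#' Blend a relationship matrix with the identity
#'
#' `G* = (1 - alpha) G + alpha I`, guaranteeing positive definiteness (for
#' `alpha > 0` and PSD input) so the matrix can be inverted in the
#' mixed-model equations.
#'
#' @param m A relationship matrix.
#' @param alpha Blending weight in \[0, 1).
#' @return The conditioned matrix, same class and `kind`, with attribute
#'   `blended = alpha`.
#' @export
condition_relmat <- function(m, alpha = 0.01) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (alpha == 0) return(m)
  out <- (1 - alpha) * m
  diag(out) <- diag(out) + alpha
  attr(out, "kind") <- attr(m, "kind")
  attr(out, "blended") <- alpha
  class(out) <- c("relmat", "matrix", "array")
  out
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d individuals, mean diagonal %.3f\n",
              if (is.null(attr(x, "kind"))) "additive" else attr(x, "kind"),
              nrow(x), mean(diag(x))))
  invisible(x)
}
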