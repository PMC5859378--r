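# SNP-based parentage assignment by trio Mendelian exclusion over all
# candidate sire x dam pairs, with a genotyping-error tolerance.

# Incompatibility rule for one trio of dosages (offspring receives one
# gamete per parent; dosage 0 -> gamete {0}, 1 -> {0,1}, 2 -> {1}).
.trio_incompatible <- function(s, d, o) {
  (o == 0L & (s == 2L | d == 2L)) |
    (o == 2L & (s == 0L | d == 0L)) |
    (o == 1L & ((s == 0L & d == 0L) | (s == 2L & d == 2L)))
}

#' Trio mismatch rate
#'
#' Counts loci at which an offspring's dosage is Mendelian-impossible given
#' a candidate parental pair. A locus is comparable iff all three genotypes
#' are non-missing; the rate is mismatches / comparable loci.
#'
#' @param offspring,sire,dam Dosage vectors in \{0, 1, 2, NA\} over a shared
#'   locus index.
#' @return A list with `rate` (NA if no comparable locus), `mismatches` and
#'   `compared`.
#' @export
trio_mismatch_rate <- function(offspring, sire, dam) {
  stopifnot(length(offspring) == length(sire), length(sire) == length(dam))
  ok <- !is.na(offspring) & !is.na(sire) & !is.na(dam)
  mm <- sum(.trio_incompatible(sire[ok], dam[ok], offspring[ok]))
  n <- sum(ok)
  list(rate = if (n > 0) mm / n else NA_real_, mismatches = mm, compared = n)
}

# loci-major (loci x individuals) integer matrix with missing coded 3
.code_loci_major <- function(g) {
  x <- t(g)
  x[is.na(x)] <- 3L
  storage.mode(x) <- "integer"
  x
}

#' Assign offspring to sire-dam pairs
#'
#' Evaluates the trio mismatch rate of every candidate sire x dam pair for
#' every offspring (compiled scan) and assigns the minimal-mismatch pair iff
#' its rate is at most `tolerance` and the runner-up pair is worse by at
#' least `margin` (uniqueness). Exact ties are never assigned; candidate
#' order does not affect the result.
#'
#' @param offspring,sires,dams Dosage matrices (individuals x loci, shared
#'   locus columns) with rownames as ids.
#' @param tolerance Maximum mismatch rate of the best pair (default 0.04,
#'   an overall genotyping-error allowance).
#' @param margin Minimum absolute rate difference between runner-up and best
#'   pair for a unique assignment.
#' @return An object of class `parentage_result`: `assignments` data frame
#'   (offspring_id, sire_id, dam_id, mismatch_rate, runner_up_rate,
#'   compared, status in assigned/ambiguous/unassigned) and a `summary`
#'   list (n_assigned, family sizes, per-parent contributions).
#' @export
assign_parentage <- function(offspring, sires, dams, tolerance = 0.04,
                             margin = 0.01) {
  if (tolerance < 0 || tolerance > 1) stop("tolerance must lie in [0, 1]")
  if (nrow(sires) == 0 || nrow(dams) == 0) stop("empty candidate parent set")
  common <- Reduce(intersect, list(colnames(offspring), colnames(sires),
                                   colnames(dams)))
  if (length(common) == 0) stop("no shared loci between offspring and parents")
  scan <- .trio_scan(.code_loci_major(offspring[, common, drop = FALSE]),
                     .code_loci_major(sires[, common, drop = FALSE]),
                     .code_loci_major(dams[, common, drop = FALSE]))
  rate <- scan$mismatch / scan$compared
  rate[scan$compared == 0] <- NA_real_
  ns <- nrow(sires); nd <- nrow(dams)
  pair_sire <- rep(rownames(sires), each = nd)
  pair_dam <- rep(rownames(dams), times = ns)
  n_off <- nrow(offspring)
  res <- data.frame(offspring_id = rownames(offspring),
                    sire_id = NA_character_, dam_id = NA_character_,
                    mismatch_rate = NA_real_, runner_up_rate = NA_real_,
                    compared = NA_integer_, status = "unassigned",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_off)) {
    r <- rate[i, ]
    if (all(is.na(r))) next
    best <- which.min(r)
    r2 <- r[-best]
    runner <- if (length(r2)) min(r2, na.rm = TRUE) else Inf
    res$sire_id[i] <- pair_sire[best]
    res$dam_id[i] <- pair_dam[best]
    res$mismatch_rate[i] <- r[best]
    res$runner_up_rate[i] <- if (is.finite(runner)) runner else NA_real_
    res$compared[i] <- scan$compared[i, best]
    if (r[best] <= tolerance) {
      gap <- runner - r[best]
      res$status[i] <- if (is.finite(gap) && gap >= margin && gap > 0)
        "assigned" else "ambiguous"
    }
  }
  asg <- res[res$status == "assigned", ]
  fam <- if (nrow(asg)) table(paste(asg$sire_id, asg$dam_id)) else table(character())
  summary <- list(
    n_offspring = n_off, n_assigned = nrow(asg),
    n_families = length(fam), family_sizes = as.integer(fam),
    sire_contrib = if (nrow(asg)) table(asg$sire_id) else table(character()),
    dam_contrib = if (nrow(asg)) table(asg$dam_id) else table(character()))
  structure(list(assignments = res, summary = summary,
                 tolerance = tolerance, margin = margin),
            class = "parentage_result")
}

#' @export
print.parentage_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Parentage assignment: %d / %d offspring uniquely assigned (tol %.3f)\n",
              s$n_assigned, s$n_offspring, x$tolerance))
  if (s$n_assigned > 0)
    cat(sprintf("  %d full-sib families, sizes %d-%d (mean %.1f)\n",
                s$n_families, min(s$family_sizes), max(s$family_sizes),
                mean(s$family_sizes)))
  invisible(x)
}

#' Convert assignments to a pedigree
#'
#' Keeps uniquely assigned offspring and prepends founder rows for all
#' candidate parents seen in the assignments.
#'
#' @param x A [assign_parentage()] result.
#' @param block Optional named vector mapping parent id to block; offspring
#'   inherit the block of their assigned sire.
#' @return Pedigree data frame (id, sire, dam, block).
#' @export
assignment_pedigree <- function(x, block = NULL) {
  asg <- x$assignments[x$assignments$status == "assigned", ]
  parents <- unique(c(asg$sire_id, asg$dam_id))
  blk <- function(id) if (is.null(block)) NA_integer_ else unname(block[id])
  rbind(
    data.frame(id = parents, sire = "0", dam = "0", block = blk(parents)),
    data.frame(id = asg$offspring_id, sire = asg$sire_id, dam = asg$dam_id,
               block = blk(asg$sire_id))
  )
}

#' Re-check assigned parent-offspring links
#'
#' Computes the opposing-homozygote rate (loci where one individual is
#' dosage 0 and the other 2, over loci non-missing in both) for every
#' parent-offspring link in a pedigree, and flags links above `threshold`.
#'
#' @param pedigree Pedigree data frame (id, sire, dam).
#' @param g Dosage matrix with rownames covering the pedigree ids.
#' @param threshold Maximum tolerated opposing-homozygote rate.
#' @return Data frame of links (offspring, parent, role, rate, compared,
#'   flagged).
#' @export
validate_pedigree <- function(pedigree, g, threshold = 0.04) {
  off <- pedigree[pedigree$sire != "0" | pedigree$dam != "0", ]
  links <- rbind(
    data.frame(offspring = off$id, parent = off$sire, role = "sire"),
    data.frame(offspring = off$id, parent = off$dam, role = "dam"))
  links <- links[links$parent != "0", ]
  rate <- numeric(nrow(links)); compared <- integer(nrow(links))
  for (k in seq_len(nrow(links))) {
    a <- g[links$offspring[k], ]; b <- g[links$parent[k], ]
    ok <- !is.na(a) & !is.na(b)
    opp <- sum((a[ok] == 0L & b[ok] == 2L) | (a[ok] == 2L & b[ok] == 0L))
    compared[k] <- sum(ok)
    rate[k] <- if (compared[k] > 0) opp / compared[k] else NA_real_
  }
  links$rate <- rate
  links$compared <- compared
  links$flagged <- !is.na(rate) & rate > threshold
  links
}
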