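# Fixed 50-linkage-group genome template for the Amur mirror carp cross.

# Consensus linkage-map layout: 50 linkage groups with their genetic lengths
# (cM) and the number of mapped SNP markers on each. Total 3,944 cM and
# 12,311 markers. Used as the default genome for all simulations.
.carp_linkage_map <- data.frame(
  lg = 1:50,
  length_cm = c(102, 91, 76, 77, 90, 77, 77, 77, 75, 84,
                83, 71, 81, 70, 69, 78, 105, 78, 92, 75,
                106, 75, 84, 70, 76, 77, 71, 84, 93, 81,
                71, 77, 78, 70, 87, 77, 88, 77, 73, 71,
                74, 72, 72, 79, 80, 67, 73, 71, 75, 69),
  n_markers = c(350, 350, 325, 322, 319, 315, 311, 292, 290, 287,
                283, 277, 272, 263, 260, 259, 257, 256, 249, 249,
                246, 245, 241, 241, 240, 239, 238, 237, 237, 236,
                229, 229, 227, 227, 226, 225, 222, 221, 215, 213,
                212, 212, 208, 203, 199, 193, 175, 169, 163, 157)
)

#' Carp linkage-map template
#'
#' Returns the fixed 50-linkage-group layout of the carp consensus linkage
#' map used as the simulation genome: genetic length (cM) and mapped marker
#' count per group (3,944 cM and 12,311 markers in total).
#'
#' @return A data frame with columns `lg`, `length_cm` and `n_markers`.
#' @export
carp_linkage_map <- function() .carp_linkage_map

# Largest-remainder apportionment of `n` items over non-negative weights,
# with optional minimum of one item per class.
.apportion <- function(n, weights, min_one = FALSE) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- n * weights / sum(weights)
  alloc <- floor(quota)
  if (min_one) alloc <- pmax(alloc, 1L)
  left <- n - sum(alloc)
  if (left > 0) {
    idx <- order(quota - floor(quota), decreasing = TRUE)
    take <- idx[seq_len(left)]
    alloc[take] <- alloc[take] + 1L
  } else if (left < 0) {
    # over-allocated by the min-one rule: remove from largest allocations
    # that stay >= the floor
    for (k in seq_len(-left)) {
      cand <- which(alloc > if (min_one) 1L else 0L)
      j <- cand[which.max(alloc[cand] - quota[cand])]
      alloc[j] <- alloc[j] - 1L
    }
  }
  as.integer(alloc)
}

#' Build a genome template
#'
#' Lays out marker and QTL positions on the fixed 50-linkage-group carp map.
#' Markers are apportioned across groups proportionally to the mapped marker
#' counts of the consensus map (largest-remainder method, at least one marker
#' per group); QTL are apportioned proportionally to genetic length. Within a
#' group, positions are drawn uniformly over (0, length) and sorted. QTL
#' positions are distinct from marker positions, so markers tag QTL through
#' linkage only.
#'
#' @param n_markers Total number of SNP markers (>= 50, one per group).
#' @param n_qtl Total number of QTL (>= 0).
#' @param seed Optional integer seed for reproducible positions.
#' @return An object of class `genome_template`: a list with `map` (the
#'   linkage-group table), `marker_pos` and `qtl_pos` (per-group sorted cM
#'   positions), and `marker_lg`, `qtl_lg` index vectors.
#' @examples
#' g <- genome_template(n_markers = 500, n_qtl = 100, seed = 1)
#' sum(lengths(g$marker_pos))
#' @export
genome_template <- function(n_markers = 12311L, n_qtl = 2000L, seed = NULL) {
  map <- .carp_linkage_map
  if (n_markers < nrow(map))
    stop("n_markers must be >= ", nrow(map), " (at least one marker per linkage group)")
  if (n_qtl < 0) stop("n_qtl must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_mk <- .apportion(n_markers, map$n_markers, min_one = TRUE)
  n_qt <- .apportion(n_qtl, map$length_cm)
  marker_pos <- vector("list", nrow(map))
  qtl_pos <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    L <- map$length_cm[i]
    mp <- sort(stats::runif(n_mk[i], 0, L))
    qp <- sort(stats::runif(n_qt[i], 0, L))
    # continuous positions collide with probability zero; guard anyway
    while (anyDuplicated(c(mp, qp))) qp <- sort(stats::runif(n_qt[i], 0, L))
    marker_pos[[i]] <- mp
    qtl_pos[[i]] <- qp
  }
  structure(list(
    map = map,
    marker_pos = marker_pos,
    qtl_pos = qtl_pos,
    marker_lg = rep.int(map$lg, n_mk),
    qtl_lg = rep.int(map$lg, n_qt)
  ), class = "genome_template")
}

#' @export
print.genome_template <- function(x, ...) {
  cat("Genome template:", nrow(x$map), "linkage groups,",
      sum(x$map$length_cm), "cM\n")
  cat("  markers:", length(x$marker_lg), " QTL:", length(x$qtl_lg), "\n")
  invisible(x)
}
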