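# Readers and writers for the standard exchange formats: VCF 4.2 (GT only),
# dosage TSV, pedigree CSV and phenotype CSV.

#' Read a genotype matrix
#'
#' VCF input keeps biallelic sites only (multiallelic sites are skipped with
#' a warning and counted); dosage is the ALT-allele count, missing GT gives
#' `NA`. TSV input expects the dialect written by [write_genotypes_tsv()]:
#' first column `id`, one column per marker, `NA` for missing.
#'
#' @param path Input file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return Integer dosage matrix, individuals x loci, with ids as rownames.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(v)
    if (any(!bi))
      warning(sum(!bi), " multiallelic site(s) skipped")
    v <- v[bi, ]
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dos[gt == "0/0"] <- 0L
    dos[gt == "0/1" | gt == "1/0"] <- 1L
    dos[gt == "1/1"] <- 2L
    t(dos)
  } else {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- as.character(x[[1]])
    m
  }
}

# header comment stamped on every output table
.provenance_header <- function(seed = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("carpgs")),
                  error = function(e) "dev")
  sprintf("# carpgs %s%s | %s", ver,
          if (is.null(seed)) "" else sprintf(" | seed=%s", seed),
          format(Sys.time(), "%Y-%m-%d"))
}

#' Write genotypes as VCF 4.2
#'
#' Simulated markers are placed on chromosomes `LG1..LG50` at 1-based
#' integer positions `round(cM * 1e5)`; only the GT field is written
#' (REF = A, ALT = G placeholders).
#'
#' @param g Dosage matrix (individuals x loci) in \{0, 1, 2, NA\}.
#' @param marker_info Data frame with `name`, `lg`, `pos_cm` for the columns
#'   of `g`.
#' @param path Output file.
#' @export
write_genotypes_vcf <- function(g, marker_info, path) {
  m <- match(colnames(g), marker_info$name)
  if (anyNA(m)) stop("marker_info does not cover all loci")
  gt <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", ncol(g), nrow(g))
  ok <- !is.na(t(g))
  body[ok] <- gt[t(g)[ok] + 1L]
  lines <- c("##fileformat=VCFv4.2",
             "##source=carpgs",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  pos <- pmax(1L, as.integer(round(marker_info$pos_cm[m] * 1e5)))
  rows <- paste(paste0("LG", marker_info$lg[m]), pos, colnames(g),
                "A", "G", ".", "PASS", ".", "GT",
                apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Write genotypes as a dosage TSV
#'
#' First column `id`, one column per marker, missing as `NA`.
#'
#' @inheritParams write_genotypes_vcf
#' @param seed Optional seed recorded in the header comment.
#' @export
write_genotypes_tsv <- function(g, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed), con)
  writeLines(paste(c("id", colnames(g)), collapse = "\t"), con)
  utils::write.table(data.frame(id = rownames(g), g, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write / read a pedigree CSV
#'
#' Columns id, sire, dam, block; founders have sire = dam = "0".
#'
#' @param pedigree Pedigree data frame.
#' @param path File path.
#' @param seed Optional seed recorded in the header comment.
#' @export
write_pedigree_csv <- function(pedigree, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed), con)
  utils::write.csv(pedigree, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", colClasses = c(
    id = "character", sire = "character", dam = "character"))
}

#' Write / read a phenotype CSV
#'
#' Columns id, weight_g, length_mm, cross.
#'
#' @param phenotypes Phenotype data frame.
#' @param path File path.
#' @param seed Optional seed recorded in the header comment.
#' @export
write_phenotypes_csv <- function(phenotypes, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed), con)
  utils::write.csv(phenotypes, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  x <- utils::read.csv(path, comment.char = "#",
                       colClasses = c(id = "character"))
  x$cross <- factor(x$cross)
  x
}

#' Write / read a relationship matrix as TSV
#'
#' Header row of ids; numeric rows in the same order.
#'
#' @param m Relationship matrix.
#' @param path File path.
#' @export
write_relmat_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_relmat_tsv
#' @export
read_relmat_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  structure(m, class = c("relmat", "matrix", "array"))
}
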