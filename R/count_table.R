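#' Allele-depth count tables
#'
#' A count table is the package's internal representation of per-sample
#' allele depths at biallelic SNVs: one row per variant site per sample,
#' with reference and alternative read counts and the called genotype.
#' It is a tibble with a fixed column set, validated on construction.
#'
#' Columns:
#' \describe{
#'   \item{chrom}{chromosome name (character)}
#'   \item{pos}{1-based position (integer, >= 1)}
#'   \item{ref, alt}{single-base alleles, `ref != alt`}
#'   \item{rsid}{dbSNP identifier or `NA` when the site is not in dbSNP}
#'   \item{qual}{site quality score (non-negative; `NA` when absent)}
#'   \item{gene}{gene symbol annotation or `NA`}
#'   \item{sample}{sample identifier}
#'   \item{ref_count, alt_count}{non-negative integer read counts}
#'   \item{genotype}{one of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`}
#' }
#'
#' @param x A data frame with the columns above.
#' @return A validated tibble of class `aei_count_table`.
#' @examples
#' as_count_table(data.frame(
#'   chrom = "chr11", pos = 61717852L, ref = "C", alt = "T",
#'   rsid = "rs149698", qual = 500, gene = "BEST1",
#'   sample = "S01", ref_count = 30L, alt_count = 20L, genotype = "het"
#' ))
#' @export
as_count_table <- function(x) {
  required <- c("chrom", "pos", "ref", "alt", "rsid", "qual", "gene",
                "sample", "ref_count", "alt_count", "genotype")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("count table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as_tibble(x)[required]
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$ref <- as.character(x$ref)
  x$alt <- as.character(x$alt)
  x$rsid <- as.character(x$rsid)
  x$qual <- as.numeric(x$qual)
  x$gene <- as.character(x$gene)
  x$sample <- as.character(x$sample)
  x$ref_count <- as.integer(x$ref_count)
  x$alt_count <- as.integer(x$alt_count)
  x$genotype <- as.character(x$genotype)
  validate_count_table(x)
  class(x) <- c("aei_count_table", class(x))
  x
}

validate_count_table <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$pos)) || any(x$pos < 1)) {
    stop("count table: 'pos' must be a 1-based position >= 1", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  if (!all(x$ref %in% bases) || !all(x$alt %in% bases)) {
    stop("count table: only single-base SNV alleles (A/C/G/T) are supported",
         call. = FALSE)
  }
  if (any(x$ref == x$alt)) {
    stop("count table: ref and alt alleles must differ", call. = FALSE)
  }
  if (any(is.na(x$ref_count)) || any(is.na(x$alt_count)) ||
      any(x$ref_count < 0) || any(x$alt_count < 0)) {
    stop("count table: read counts must be non-negative integers",
         call. = FALSE)
  }
  if (any(!is.na(x$qual) & x$qual < 0)) {
    stop("count table: 'qual' must be non-negative", call. = FALSE)
  }
  ok_gt <- c("hom_ref", "het", "hom_alt", "missing")
  if (!all(x$genotype %in% ok_gt)) {
    bad <- setdiff(unique(x$genotype), ok_gt)
    stop("count table: invalid genotype value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(x$chrom, x$pos, x$ref, x$alt, x$sample, sep = "\r")
  if (anyDuplicated(key)) {
    stop("count table: duplicate (site, sample) records", call. = FALSE)
  }
  invisible(x)
}

#' Variant identifier strings
#'
#' Builds a `chrom:pos_ref>alt` label for each row of a count table,
#' call set or summary table; used as the join key throughout.
#'
#' @param x A data frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector of variant labels.
#' @export
variant_id <- function(x) {
  paste0(x$chrom, ":", x$pos, "_", x$ref, ">", x$alt)
}

#' @export
print.aei_count_table <- function(x, ...) {
  n_sites <- length(unique(variant_id(x)))
  n_samples <- length(unique(x$sample))
  cat(sprintf("<aei_count_table> %d records: %d sites x %d samples\n",
              nrow(x), n_sites, n_samples))
  NextMethod()
}
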