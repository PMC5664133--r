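#' Read a multi-sample VCF into a count table
#'
#' Reads a VCF 4.x file (plain or gzipped) with per-sample `GT` and `AD`
#' fields and converts every retained biallelic SNV into one allele-depth
#' record per sample. Sites whose `ID` column is `"."` get `rsid = NA`.
#' Records with a missing `AD` value are kept with zero counts and
#' `genotype = "missing"`; records lacking `GT` are likewise `"missing"`.
#' A `GENE=` key in the INFO column, when present, populates the gene
#' annotation.
#'
#' @param path Path to a VCF file.
#' @param drop_nonbiallelic Drop multi-allelic and indel records
#'   (default `TRUE`). With `FALSE` the function refuses files containing
#'   such records instead of silently representing them.
#' @return An [as_count_table()] tibble with one record per sample per
#'   retained site. The number of dropped non-biallelic/indel records is
#'   attached as attribute `"n_dropped_nonbiallelic"` and reported via
#'   [message()].
#' @export
read_vcf <- function(path, drop_nonbiallelic = TRUE) {
  if (!file.exists(path)) {
    stop("cannot read VCF: no such file: ", path, call. = FALSE)
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("cannot read VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    message("read_vcf: no variant records in ", path)
    empty <- as_count_table(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), rsid = character(), qual = numeric(),
      gene = character(), sample = character(), ref_count = integer(),
      alt_count = integer(), genotype = character()
    ))
    attr(empty, "n_dropped_nonbiallelic") <- 0L
    return(empty)
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic_snv <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_dropped <- sum(!biallelic_snv)
  if (n_dropped > 0) {
    if (!drop_nonbiallelic) {
      stop("VCF contains ", n_dropped, " non-biallelic-SNV record(s) and ",
           "drop_nonbiallelic = FALSE", call. = FALSE)
    }
    message("read_vcf: dropped ", n_dropped,
            " non-biallelic or non-SNV record(s)")
  }

  # file line number of each record, for format diagnostics
  header_lines <- length(vcf@meta) + 1L
  line_no <- header_lines + seq_len(nrow(fix))

  keep <- which(biallelic_snv)
  samples <- colnames(vcf@gt)[-1]
  if (length(keep) == 0 || length(samples) == 0) {
    empty <- as_count_table(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), rsid = character(), qual = numeric(),
      gene = character(), sample = character(), ref_count = integer(),
      alt_count = integer(), genotype = character()
    ))
    attr(empty, "n_dropped_nonbiallelic") <- n_dropped
    return(empty)
  }

  sub <- vcf
  sub@fix <- fix[keep, , drop = FALSE]
  sub@gt <- vcf@gt[keep, , drop = FALSE]
  line_no <- line_no[keep]

  gt <- vcfR::extract.gt(sub, element = "GT", IDtoRowNames = FALSE)
  ad <- vcfR::extract.gt(sub, element = "AD", IDtoRowNames = FALSE)

  info <- sub@fix[, "INFO"]
  gene <- ifelse(grepl("(^|;)GENE=", info),
                 sub(".*(?:^|;)GENE=([^;]*).*", "\\1", info), NA_character_)

  n_sites <- nrow(sub@fix)
  n_samp <- length(samples)

  ad_vec <- as.vector(ad)  # column-major: site varies fastest
  gt_vec <- as.vector(gt)
  ad_missing <- is.na(ad_vec) | ad_vec == "." | ad_vec == ""
  ref_count <- integer(length(ad_vec))
  alt_count <- integer(length(ad_vec))
  if (any(!ad_missing)) {
    parts <- strsplit(ad_vec[!ad_missing], ",", fixed = TRUE)
    arity <- lengths(parts)
    if (any(arity != 2)) {
      bad <- which(!ad_missing)[which(arity != 2)[1]]
      bad_site <- ((bad - 1) %% n_sites) + 1
      stop(sprintf(
        "VCF format error at line %d (%s:%s): AD has %d value(s), expected 2 for a biallelic site",
        line_no[bad_site], sub@fix[bad_site, "CHROM"],
        sub@fix[bad_site, "POS"], arity[which(arity != 2)[1]]),
        call. = FALSE)
    }
    mat <- matrix(suppressWarnings(as.integer(unlist(parts))),
                  ncol = 2, byrow = TRUE)
    if (anyNA(mat)) {
      stop("VCF format error: non-integer AD value", call. = FALSE)
    }
    ref_count[!ad_missing] <- mat[, 1]
    alt_count[!ad_missing] <- mat[, 2]
  }

  genotype <- parse_gt(gt_vec)
  genotype[ad_missing] <- "missing"

  qual <- suppressWarnings(as.numeric(sub@fix[, "QUAL"]))
  rsid <- sub@fix[, "ID"]
  rsid[is.na(rsid) | rsid == "."] <- NA_character_

  out <- tibble(
    chrom = rep(sub@fix[, "CHROM"], times = n_samp),
    pos = rep(as.integer(sub@fix[, "POS"]), times = n_samp),
    ref = rep(sub@fix[, "REF"], times = n_samp),
    alt = rep(sub@fix[, "ALT"], times = n_samp),
    rsid = rep(rsid, times = n_samp),
    qual = rep(qual, times = n_samp),
    gene = rep(gene, times = n_samp),
    sample = rep(samples, each = n_sites),
    ref_count = ref_count,
    alt_count = alt_count,
    genotype = genotype
  )
  out <- as_count_table(out)
  attr(out, "n_dropped_nonbiallelic") <- n_dropped
  out
}

parse_gt <- function(gt) {
  out <- rep("missing", length(gt))
  gt <- sub(":.*$", "", gt)
  known <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- strsplit(gt[known], "[/|]")
  cls <- vapply(alleles, function(a) {
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a)) return("missing")
    if (all(a == 0)) return("hom_ref")
    if (all(a == 1)) return("hom_alt")
    if (setequal(a, c(0L, 1L))) return("het")
    "missing"  # alleles beyond the first alt cannot occur post biallelic filter
  }, character(1))
  out[known] <- cls
  out
}

#' Write a count table as VCF
#'
#' Emits one VCF record per site with `GT:AD:DP` per-sample fields, the
#' gene annotation (when present) as a `GENE=` INFO key, and the rsid in
#' the ID column. The file is gzip-compressed (use a `.vcf.gz` path).
#'
#' @param table An [as_count_table()] tibble.
#' @param path Output path, conventionally ending in `.vcf.gz`.
#' @return The path, invisibly.
#' @export
write_vcf <- function(table, path) {
  table <- as_count_table(table)
  sites <- dplyr::distinct(
    table, .data$chrom, .data$pos, .data$ref, .data$alt,
    .data$rsid, .data$qual, .data$gene
  )
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos, .data$ref, .data$alt)
  samples <- sort(unique(table$sample))

  info <- ifelse(is.na(sites$gene), ".", paste0("GENE=", sites$gene))
  fix <- cbind(
    CHROM = sites$chrom,
    POS = as.character(sites$pos),
    ID = ifelse(is.na(sites$rsid), ".", sites$rsid),
    REF = sites$ref,
    ALT = sites$alt,
    QUAL = ifelse(is.na(sites$qual), ".", format(sites$qual, trim = TRUE,
                                                 scientific = FALSE)),
    FILTER = "PASS",
    INFO = info
  )

  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  site_idx <- match(key(table), key(sites))
  samp_idx <- match(table$sample, samples)
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")[table$genotype]
  cell <- ifelse(
    table$genotype == "missing" & table$ref_count + table$alt_count == 0,
    "./.:.:.",
    paste0(gt_code, ":", table$ref_count, ",", table$alt_count,
           ":", table$ref_count + table$alt_count)
  )
  gt <- matrix("./.:.:.", nrow = nrow(sites), ncol = length(samples),
               dimnames = list(NULL, samples))
  gt[cbind(site_idx, samp_idx)] <- cell
  gt <- cbind(FORMAT = "GT:AD:DP", gt)

  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=aeiscan",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"
  )
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

count_table_cols <- c("chrom", "pos", "ref", "alt", "rsid", "qual", "gene",
                      "sample", "ref_count", "alt_count", "genotype")

#' Read and write tab-separated count tables
#'
#' The tab-separated equivalent of the VCF input: one row per (site,
#' sample) with header `chrom, pos, ref, alt, rsid, qual, gene, sample,
#' ref_count, alt_count, genotype`. `read_count_table()` and
#' [write_count_table()] round-trip losslessly.
#'
#' @param path Path to a tab-separated file.
#' @return An [as_count_table()] tibble.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read count table: no such file: ", path, call. = FALSE)
  }
  # a column check follows, so readr's own spec-mismatch warning is noise
  x <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    rsid = readr::col_character(), qual = readr::col_double(),
    gene = readr::col_character(), sample = readr::col_character(),
    ref_count = readr::col_integer(), alt_count = readr::col_integer(),
    genotype = readr::col_character()
  ), progress = FALSE))
  missing_cols <- setdiff(count_table_cols, names(x))
  if (length(missing_cols) > 0) {
    stop("count table file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_count_table(x)
}

#' @rdname read_count_table
#' @param table An [as_count_table()] tibble to write.
#' @export
write_count_table <- function(table, path) {
  table <- as_count_table(table)
  readr::write_tsv(as_tibble(table)[count_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Write a per-variant AEI summary table
#'
#' Emits the cohort report: one row per variant with the heterozygote
#' count, directional imbalance counts, AEI frequencies, oriented mean
#' allelic ratio with SEM, and excess kurtosis with SEK. Percentages are
#' printed to one decimal, ratios and SEM to three decimals, kurtosis and
#' SEK to four significant figures.
#'
#' @param summaries A summary tibble from [summarize_cohort()].
#' @param path Output path for the tab-separated report.
#' @return The path, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  fmt1 <- function(x) ifelse(is.na(x), NA, sprintf("%.1f", x))
  fmt3 <- function(x) ifelse(is.na(x), NA, sprintf("%.3f", x))
  fmt4 <- function(x) ifelse(is.na(x), NA, formatC(signif(x, 4),
                                                   format = "fg", flag = "#"))
  label <- ifelse(is.na(summaries$gene), variant_id(summaries),
                  paste0(summaries$gene, "_",
                         ifelse(is.na(summaries$rsid),
                                variant_id(summaries), summaries$rsid)))
  out <- tibble(
    gene_snp = label,
    n_het = summaries$n_het,
    n_ratio_below = summaries$n_below,
    n_ratio_above = summaries$n_above,
    n_imbalanced = summaries$n_imbalanced,
    freq_het_pct = fmt1(summaries$freq_het),
    freq_cohort_pct = fmt1(summaries$freq_cohort),
    abs_mean_ratio = fmt3(summaries$abs_mean_ratio),
    sem_ratio = fmt3(summaries$sem_ratio),
    kurtosis = fmt4(summaries$kurtosis),
    sek = fmt4(summaries$sek)
  )
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_snp = readr::col_character(),
    .default = readr::col_double()
  ), na = "NA", progress = FALSE)
}
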