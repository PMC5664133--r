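#' Read pyrosequencing allele-quantification measurements
#'
#' Input is tab-separated with header `sample, rsid, level, replicate,
#' allele_a_percent`: one row per technical replicate, with `level`
#' either `DNA` (genomic, e.g. scleral DNA) or `RNA` (cDNA), and the
#' allele A percentage in \[0, 100\] (allele B is the complement).
#'
#' @param path Path to the measurements file.
#' @return A validated tibble.
#' @export
read_pyro_measurements <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read pyro measurements: no such file: ", path,
         call. = FALSE)
  }
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), rsid = readr::col_character(),
    level = readr::col_character(), replicate = readr::col_character(),
    allele_a_percent = readr::col_double()
  ), progress = FALSE)
  required <- c("sample", "rsid", "level", "replicate", "allele_a_percent")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("pyro measurements file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(x$level %in% c("DNA", "RNA"))) {
    stop("pyro measurements: 'level' must be DNA or RNA", call. = FALSE)
  }
  if (any(x$allele_a_percent < 0 | x$allele_a_percent > 100)) {
    stop("pyro measurements: allele percentages must lie in [0, 100]",
         call. = FALSE)
  }
  x
}

#' Aggregate technical replicates
#'
#' Mean and SEM (n - 1 sample SD over sqrt(n)) of replicate allele
#' percentages for one sample/SNP/level. A single replicate yields SEM 0
#' with a warning.
#'
#' @param percents Numeric vector of replicate allele A percentages,
#'   length >= 1.
#' @return A list with `mean`, `sem`, `n`.
#' @examples
#' aggregate_replicates(c(30, 40))  # mean 35, SEM 5
#' @export
aggregate_replicates <- function(percents) {
  n <- length(percents)
  if (n == 0) {
    stop("aggregate_replicates: empty input", call. = FALSE)
  }
  if (n == 1) {
    warning("aggregate_replicates: single replicate; SEM reported as 0",
            call. = FALSE)
    return(list(mean = percents, sem = 0, n = 1L))
  }
  list(mean = mean(percents), sem = stats::sd(percents) / sqrt(n), n = n)
}

#' Classify allelic balance of a mean allele percentage
#'
#' Balanced means the mean allele A percentage lies inside the balance
#' band, inclusive of its boundaries (default 40-60%).
#'
#' @param mean_percent Numeric vector in \[0, 100\].
#' @param band Lower and upper band bounds, default `c(40, 60)`.
#' @return Logical vector.
#' @examples
#' classify_balance(c(50, 60, 64.1))  # TRUE TRUE FALSE
#' @export
classify_balance <- function(mean_percent, band = c(40, 60)) {
  stopifnot(length(band) == 2, band[1] < band[2],
            all(mean_percent >= 0 & mean_percent <= 100))
  mean_percent >= band[1] & mean_percent <= band[2]
}

#' Confirm AEI from paired DNA and RNA assays
#'
#' AEI is confirmed for a sample/SNP when the DNA-level assay is balanced
#' (both alleles present at comparable dose, ruling out genomic causes)
#' while the RNA-level assay is imbalanced. An unbalanced DNA assay
#' invalidates the comparison: the result is flagged, never confirmed.
#'
#' @param dna,rna Aggregated results from [aggregate_replicates()] for
#'   the DNA and RNA level of one sample/SNP. Pass `NULL` for a missing
#'   level to get an error naming it.
#' @param sample_id,rsid Identifiers carried into the result.
#' @param band Balance band, default `c(40, 60)`.
#' @return A one-row tibble with means, SEMs, replicate counts, balance
#'   flags, `dna_unbalanced` and `aei_confirmed`.
#' @export
confirm_aei <- function(dna, rna, sample_id = NA_character_,
                        rsid = NA_character_, band = c(40, 60)) {
  for (lv in c("dna", "rna")) {
    if (is.null(get(lv))) {
      stop(sprintf("confirm_aei: missing %s-level measurement for %s/%s",
                   toupper(lv), sample_id, rsid), call. = FALSE)
    }
  }
  dna_bal <- classify_balance(dna$mean, band)
  rna_bal <- classify_balance(rna$mean, band)
  tibble(
    sample = sample_id, rsid = rsid,
    dna_mean = dna$mean, dna_sem = dna$sem, dna_n = dna$n,
    rna_mean = rna$mean, rna_sem = rna$sem, rna_n = rna$n,
    dna_balanced = dna_bal, rna_balanced = rna_bal,
    dna_unbalanced = !dna_bal,
    aei_confirmed = dna_bal & !rna_bal
  )
}

#' Run the pyrosequencing DNA-vs-RNA comparison
#'
#' Aggregates technical replicates per sample/SNP/level and classifies
#' each sample/SNP: AEI is confirmed when the DNA level is balanced and
#' the RNA level is not. Every sample/SNP must carry both levels.
#'
#' @param measurements A tibble from [read_pyro_measurements()] (or with
#'   the same columns).
#' @param band Balance band in percent, default `c(40, 60)`.
#' @return A tibble with one row per sample/SNP.
#' @export
pyro_validate <- function(measurements, band = c(40, 60)) {
  if (nrow(measurements) == 0) {
    return(tibble(
      sample = character(), rsid = character(),
      dna_mean = numeric(), dna_sem = numeric(), dna_n = integer(),
      rna_mean = numeric(), rna_sem = numeric(), rna_n = integer(),
      dna_balanced = logical(), rna_balanced = logical(),
      dna_unbalanced = logical(), aei_confirmed = logical()
    ))
  }
  groups <- split(measurements,
                  paste(measurements$sample, measurements$rsid, sep = "\r"))
  out <- lapply(groups, function(g) {
    agg <- function(lv) {
      v <- g$allele_a_percent[g$level == lv]
      if (length(v) == 0) return(NULL)
      suppressWarnings(aggregate_replicates(v))
    }
    confirm_aei(agg("DNA"), agg("RNA"),
                sample_id = g$sample[1], rsid = g$rsid[1], band = band)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$sample, .data$rsid)
}

#' @rdname pyro_validate
#' @param results A tibble returned by `pyro_validate()`.
#' @param path Output path for the tab-separated results.
#' @export
write_pyro_results <- function(results, path) {
  readr::write_tsv(results, path, na = "NA", progress = FALSE)
  invisible(path)
}
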