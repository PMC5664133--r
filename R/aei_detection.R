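#' Variant-selection and outlier configuration
#'
#' Bundles the thresholds of the AEI scan. Defaults follow the published
#' analysis: site quality strictly greater than 225, total coverage of at
#' least 20 reads, each allele supported by at least two reads, the site
#' reported in dbSNP (operationalized as a non-missing rsID), outliers
#' defined per sample as log allelic ratios outside mean +/- 2 SD, and a
#' moderate-imbalance band of linear ratios strictly outside
#' \[0.666, 1.5\] (allele percentages outside 40-60%).
#'
#' @param min_qual Site quality threshold; records must have
#'   `qual > min_qual` (strict). Default 225.
#' @param min_depth Minimum total reads (`ref_count + alt_count`),
#'   at-least. Default 20.
#' @param min_allele_reads Minimum reads supporting each allele,
#'   at-least. Default 2.
#' @param require_rsid Require a non-missing rsID (dbSNP membership),
#'   default `TRUE`. An optional `rsid_allowlist` restricts further.
#' @param outlier_scope Reference population for the outlier model:
#'   `"per_sample"` (all passing variants within one sample, the default)
#'   or `"per_variant"` (all passing samples within one variant).
#' @param k_sd Number of standard deviations defining outliers. Default 2.
#' @param ratio_low,ratio_high Moderate-imbalance band bounds on the
#'   linear ratio (strict: boundary values are balanced). Defaults 0.666
#'   and 1.5.
#' @param rsid_allowlist Optional character vector of rsIDs; when given,
#'   only listed rsIDs count as dbSNP members.
#' @return A list of class `aei_config`.
#' @export
aei_config <- function(min_qual = 225, min_depth = 20, min_allele_reads = 2,
                       require_rsid = TRUE,
                       outlier_scope = c("per_sample", "per_variant"),
                       k_sd = 2, ratio_low = 0.666, ratio_high = 1.5,
                       rsid_allowlist = NULL) {
  outlier_scope <- match.arg(outlier_scope)
  stopifnot(min_qual >= 0, min_depth >= 0, min_allele_reads >= 0,
            k_sd > 0, ratio_low > 0, ratio_high > ratio_low)
  structure(
    list(min_qual = min_qual, min_depth = min_depth,
         min_allele_reads = min_allele_reads, require_rsid = require_rsid,
         outlier_scope = outlier_scope, k_sd = k_sd,
         ratio_low = ratio_low, ratio_high = ratio_high,
         rsid_allowlist = rsid_allowlist),
    class = "aei_config"
  )
}

#' @export
print.aei_config <- function(x, ...) {
  cat("<aei_config>\n")
  cat(sprintf("  filters: qual > %g, depth >= %g, reads/allele >= %g, rsid %s\n",
              x$min_qual, x$min_depth, x$min_allele_reads,
              if (x$require_rsid) "required" else "optional"))
  cat(sprintf("  outliers: %s scope, mean +/- %g SD on log ratios\n",
              x$outlier_scope, x$k_sd))
  cat(sprintf("  moderate band: linear ratio outside (%g, %g)\n",
              x$ratio_low, x$ratio_high))
  invisible(x)
}

#' Read a key=value configuration file
#'
#' Parses a plain-text configuration with one `key = value` pair per
#' line (`#` comments allowed) into an [aei_config()]. Unknown keys
#' produce a warning and are ignored.
#'
#' @param path Path to the configuration file.
#' @return An [aei_config()] object.
#' @export
read_aei_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("config format error at line: '", lines[which(bad)[1]], "'",
         call. = FALSE)
  }
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  known <- c("min_qual", "min_depth", "min_allele_reads", "require_rsid",
             "outlier_scope", "k_sd", "ratio_low", "ratio_high")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- list()
  for (k in intersect(keys, known)) {
    v <- vals[match(k, keys)]
    args[[k]] <- switch(k,
      require_rsid = toupper(v) %in% c("TRUE", "T", "YES", "1"),
      outlier_scope = v,
      as.numeric(v)
    )
  }
  do.call(aei_config, args)
}

#' Variant-selection filter
#'
#' Tests each allele-depth record against the selection filters: the
#' record must be heterozygous, have site quality strictly above
#' `min_qual`, total depth of at least `min_depth`, at least
#' `min_allele_reads` reads supporting each allele, and (when required) a
#' non-missing rsID.
#'
#' @param records A count table (or any data frame with its columns).
#' @param config An [aei_config()].
#' @return Logical vector, one element per record.
#' @examples
#' rec <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
#'                   rsid = "rs1", qual = 500, gene = NA, sample = "S1",
#'                   ref_count = 30L, alt_count = 20L, genotype = "het")
#' passes_filters(rec, aei_config())
#' @export
passes_filters <- function(records, config = aei_config()) {
  qual_ok <- !is.na(records$qual) & records$qual > config$min_qual
  depth_ok <- records$ref_count + records$alt_count >= config$min_depth
  allele_ok <- pmin(records$ref_count, records$alt_count) >=
    config$min_allele_reads
  rsid_ok <- if (config$require_rsid) {
    ok <- !is.na(records$rsid)
    if (!is.null(config$rsid_allowlist)) {
      ok <- ok & records$rsid %in% config$rsid_allowlist
    }
    ok
  } else {
    rep(TRUE, nrow(records))
  }
  records$genotype == "het" & qual_ok & depth_ok & allele_ok & rsid_ok
}

#' Per-sample allelic ratios
#'
#' Computes, for records that passed the selection filters, the linear
#' allelic ratio `alt_count / ref_count` and its natural logarithm.
#'
#' @param records Filtered records (both counts must be positive;
#'   guaranteed when `min_allele_reads >= 1`).
#' @return The records with `linear_ratio` and `log_ratio` columns
#'   appended and `is_outlier`/`is_moderate` flag columns initialized to
#'   `NA`.
#' @export
compute_ratios <- function(records) {
  if (any(records$ref_count == 0 | records$alt_count == 0)) {
    stop("compute_ratios: zero read count; ratios are only defined for ",
         "records passing the per-allele read filter", call. = FALSE)
  }
  records$linear_ratio <- records$alt_count / records$ref_count
  records$log_ratio <- log(records$linear_ratio)
  records$is_outlier <- NA
  records$is_moderate <- NA
  records
}

#' Moderate-imbalance flag
#'
#' A linear allelic ratio is moderately imbalanced when it falls strictly
#' outside the balance band (default 0.666-1.5, i.e. one allele
#' contributing less than 40% or more than 60% of reads). Boundary values
#' are balanced.
#'
#' @param linear_ratio Positive numeric vector of linear allelic ratios.
#' @param ratio_low,ratio_high Band bounds (defaults 0.666 and 1.5).
#' @return Logical vector.
#' @examples
#' moderate_flag(c(0.5, 0.666, 1.0, 1.5, 2.0))
#' @export
moderate_flag <- function(linear_ratio, ratio_low = 0.666,
                          ratio_high = 1.5) {
  stopifnot(all(linear_ratio > 0))
  linear_ratio < ratio_low | linear_ratio > ratio_high
}

#' Empirical outlier model on log allelic ratios
#'
#' Fits the mean +/- k SD outlier rule over a reference population of log
#' ratios, assuming approximate normality. The sample standard deviation
#' (n - 1 denominator) is used. A value is an outlier when it lies
#' strictly outside `[mean - k*SD, mean + k*SD]`; with a constant
#' reference population the bounds collapse onto the mean and nothing is
#' flagged.
#'
#' @param log_ratios Numeric vector of at least 2 log ratios.
#' @param scope Label recording the reference population
#'   (`"per_sample"` or `"per_variant"`).
#' @param k Number of standard deviations (default 2).
#' @return A list of class `aei_outlier_model` with elements `mean`,
#'   `sd`, `k`, `n`, `lower`, `upper`, `scope`.
#' @export
fit_outlier_model <- function(log_ratios,
                              scope = c("per_sample", "per_variant"),
                              k = 2) {
  scope <- match.arg(scope)
  stopifnot(k > 0)
  log_ratios <- log_ratios[!is.na(log_ratios)]
  if (length(log_ratios) < 2) {
    stop("fit_outlier_model: need at least 2 values to estimate mean and SD",
         call. = FALSE)
  }
  m <- mean(log_ratios)
  s <- stats::sd(log_ratios)
  structure(
    list(mean = m, sd = s, k = k, n = length(log_ratios),
         lower = m - k * s, upper = m + k * s, scope = scope),
    class = "aei_outlier_model"
  )
}

#' @rdname fit_outlier_model
#' @param model A fitted `aei_outlier_model`.
#' @param values Log ratios to flag.
#' @return For `is_outlier()`: logical vector, `TRUE` where a value lies
#'   strictly outside the model bounds.
#' @export
is_outlier <- function(model, values) {
  stopifnot(inherits(model, "aei_outlier_model"))
  values < model$lower | values > model$upper
}

#' @export
print.aei_outlier_model <- function(x, ...) {
  cat(sprintf(
    "<aei_outlier_model> %s: mean %.4f, SD %.4f (n=%d), bounds [%.4f, %.4f]\n",
    x$scope, x$mean, x$sd, x$n, x$lower, x$upper))
  invisible(x)
}

#' Call allelic expression imbalance per variant
#'
#' Runs the full per-variant scan: selection filters, per-sample allelic
#' ratios, the empirical mean +/- k SD outlier rule (fit over the scope's
#' reference population), and the moderate-imbalance band. A variant is
#' `retained` when at least one sample is an outlier; it is
#' `retained_multi` (survives single-hit exclusion) when it has at least
#' two outlier samples, or exactly one outlier sample plus at least one
#' further sample in the moderate band.
#'
#' Samples (or variants, under `per_variant` scope) contributing fewer
#' than two passing records cannot support an outlier model; their
#' records are not flagged and a single warning is emitted.
#'
#' @param table A count table.
#' @param config An [aei_config()].
#' @return A list of class `aei_calls` with elements:
#' \describe{
#'   \item{variants}{tibble, one row per variant with at least one
#'     passing heterozygous record: site columns, `n_het`, `n_outlier`,
#'     `retained`, `retained_multi`, `is_sex_chrom`.}
#'   \item{ratios}{long tibble of per-sample ratios and flags.}
#'   \item{config}{the configuration used.}
#' }
#' @export
call_aei <- function(table, config = aei_config()) {
  table <- as_count_table(table)
  if (nrow(table) == 0) {
    stop("call_aei: empty count table", call. = FALSE)
  }
  keep <- passes_filters(table, config)
  ratios <- compute_ratios(as_tibble(table)[keep, , drop = FALSE])
  if (nrow(ratios) > 0) {
    ratios$variant <- variant_id(ratios)
    group <- if (config$outlier_scope == "per_sample") {
      ratios$sample
    } else {
      ratios$variant
    }
    flags <- rep(FALSE, nrow(ratios))
    too_small <- FALSE
    for (g in split(seq_len(nrow(ratios)), group)) {
      if (length(g) < 2) {
        too_small <- TRUE
        next
      }
      model <- fit_outlier_model(ratios$log_ratio[g],
                                 scope = config$outlier_scope,
                                 k = config$k_sd)
      flags[g] <- is_outlier(model, ratios$log_ratio[g])
    }
    if (too_small) {
      warning("call_aei: some ", sub("per_", "", config$outlier_scope),
              "(s) had fewer than 2 passing records; their records were ",
              "not eligible for outlier flagging", call. = FALSE)
    }
    ratios$is_outlier <- flags
    ratios$is_moderate <- moderate_flag(ratios$linear_ratio,
                                        config$ratio_low, config$ratio_high)
    ratios <- dplyr::arrange(ratios, .data$chrom, .data$pos, .data$ref,
                             .data$alt, .data$sample)
  } else {
    ratios$variant <- character(0)
  }

  variants <- ratios %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$rsid, .data$gene) %>%
    dplyr::summarise(
      n_het = dplyr::n(),
      n_outlier = sum(.data$is_outlier),
      n_moderate_nonoutlier = sum(.data$is_moderate & !.data$is_outlier),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      retained = .data$n_outlier >= 1,
      retained_multi = .data$n_outlier >= 2 |
        (.data$n_outlier == 1 & .data$n_moderate_nonoutlier >= 1),
      is_sex_chrom = sub("^chr", "", .data$chrom) %in% c("X", "Y")
    ) %>%
    dplyr::select(-"n_moderate_nonoutlier") %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)

  structure(list(variants = variants, ratios = as_tibble(ratios),
                 config = config),
            class = "aei_calls")
}

#' @export
print.aei_calls <- function(x, ...) {
  cat(sprintf(
    "<aei_calls> %d variants with passing het samples (%s outlier scope)\n",
    nrow(x$variants), x$config$outlier_scope))
  cat(sprintf("  retained (>=1 outlier sample): %d\n",
              sum(x$variants$retained)))
  cat(sprintf("  retained after single-hit exclusion: %d\n",
              sum(x$variants$retained_multi)))
  invisible(x)
}
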