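#' AEI frequencies
#'
#' Frequency of imbalanced samples among heterozygotes and in the whole
#' cohort, in percent. Vectorized over variants.
#'
#' @param n_imbalanced Number of imbalanced samples (0 <= n_imbalanced
#'   <= n_het).
#' @param n_het Number of heterozygous samples (>= 1).
#' @param cohort_size Total cohort size (>= n_het).
#' @return A tibble with columns `freq_het` and `freq_cohort` (percent,
#'   unrounded; report writers round to one decimal).
#' @examples
#' aei_frequencies(7, 22, 52)   # 31.8% of heterozygotes, 13.5% of cohort
#' @export
aei_frequencies <- function(n_imbalanced, n_het, cohort_size) {
  if (any(n_het == 0)) {
    stop("aei_frequencies: n_het must be >= 1 (frequency undefined)",
         call. = FALSE)
  }
  stopifnot(all(n_imbalanced >= 0), all(n_imbalanced <= n_het),
            all(n_het <= cohort_size))
  tibble(freq_het = 100 * n_imbalanced / n_het,
         freq_cohort = 100 * n_imbalanced / cohort_size)
}

#' Oriented (absolute) allelic ratio
#'
#' Re-expresses a linear allelic ratio as the lesser-expressed allele's
#' count fraction over the greater-expressed allele's, i.e. `min(r, 1/r)`,
#' always in (0, 1].
#'
#' @param linear_ratio Positive numeric vector.
#' @return Numeric vector in (0, 1].
#' @examples
#' orient_ratio(c(2, 0.5, 1))  # 0.5 0.5 1
#' @export
orient_ratio <- function(linear_ratio) {
  stopifnot(all(linear_ratio > 0))
  pmin(linear_ratio, 1 / linear_ratio)
}

#' Mean and SEM of oriented ratios
#'
#' Summarizes the strength of imbalance over a variant's imbalanced
#' samples: the arithmetic mean of the oriented ratios and its standard
#' error (sample SD with n - 1 denominator over sqrt(n)). With a single
#' value the SEM is 0 by convention, with a warning.
#'
#' @param oriented_ratios Numeric vector in (0, 1], length >= 1.
#' @return A list with elements `mean`, `sem`, `n`.
#' @export
oriented_mean_sem <- function(oriented_ratios) {
  n <- length(oriented_ratios)
  if (n == 0) {
    stop("oriented_mean_sem: empty input", call. = FALSE)
  }
  if (n == 1) {
    warning("oriented_mean_sem: single value; SEM reported as 0",
            call. = FALSE)
    return(list(mean = oriented_ratios, sem = 0, n = 1L))
  }
  list(mean = mean(oriented_ratios),
       sem = stats::sd(oriented_ratios) / sqrt(n),
       n = n)
}

#' Allele percentages from a linear ratio
#'
#' Converts a linear allelic ratio r into the pair of allele percentages
#' `100*r/(1+r)` and `100/(1+r)`, ordered minor <= major. A ratio of 1.5
#' (or its reciprocal 0.666...) corresponds to the 40-60% balance-band
#' edge.
#'
#' @param linear_ratio Positive numeric vector.
#' @return A tibble with columns `minor_percent` and `major_percent`,
#'   summing to 100.
#' @examples
#' ratio_to_percent(1.5)  # 40 / 60
#' @export
ratio_to_percent <- function(linear_ratio) {
  stopifnot(all(linear_ratio > 0))
  p_alt <- 100 * linear_ratio / (1 + linear_ratio)
  p_ref <- 100 / (1 + linear_ratio)
  tibble(minor_percent = pmin(p_alt, p_ref),
         major_percent = pmax(p_alt, p_ref))
}

#' Bias-corrected excess kurtosis (G2)
#'
#' The sample excess kurtosis with small-sample bias correction,
#' `G2 = n(n+1) / ((n-1)(n-2)(n-3)) * sum(((x - mean)/s)^4)
#'       - 3 (n-1)^2 / ((n-2)(n-3))`,
#' where `s` is the n - 1 sample standard deviation. This is the
#' convention whose standard error is given by [sek()]. High values flag
#' distributions clustered tightly around the mean.
#'
#' @param values Numeric vector; needs n >= 4 and non-zero SD, otherwise
#'   the statistic is undefined and `NA` is returned with a warning.
#' @return A single numeric value, or `NA_real_`.
#' @export
excess_kurtosis <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4) {
    warning("excess_kurtosis: undefined for n < 4; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  s <- stats::sd(values)
  if (s == 0) {
    warning("excess_kurtosis: undefined for zero variance; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  z <- (values - mean(values)) / s
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Standard errors of sample skewness and kurtosis
#'
#' Closed-form standard errors as functions of sample size only:
#' `SES = sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))` and
#' `SEK = 2 * SES * sqrt((n^2 - 1) / ((n-3)(n+5)))`.
#' SEK is reported for n >= 6; smaller n returns `NA` with a warning.
#'
#' @param n Integer vector of sample sizes.
#' @return Numeric vector of standard errors.
#' @examples
#' sek(7)   # 1.587...
#' sek(6)   # 1.741...
#' @export
sek <- function(n) {
  out <- rep(NA_real_, length(n))
  ok <- !is.na(n) & n >= 6
  if (any(!ok)) {
    warning("sek: undefined for n < 6; returning NA", call. = FALSE)
  }
  nn <- n[ok]
  out[ok] <- 2 * ses(nn) * sqrt((nn^2 - 1) / ((nn - 3) * (nn + 5)))
  out
}

#' @rdname sek
#' @export
ses <- function(n) {
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

#' Summarize one AEI call across the cohort
#'
#' Aggregates a variant's per-sample ratios into the cohort report row:
#' directional imbalance counts from the moderate band (`n_below`,
#' `n_above`, summing to `n_imbalanced`), AEI frequencies among
#' heterozygotes and in the cohort, and — over the imbalanced samples'
#' oriented ratios — the mean with SEM, the bias-corrected excess
#' kurtosis with SEK, and the orientation fraction
#' `max(n_below, n_above) / n_imbalanced` (1 when all imbalanced samples
#' tilt the same way, suggesting linkage with the causal regulatory
#' allele).
#'
#' Per-sample counting uses the moderate band, not the outlier flag: the
#' mean +/- k SD rule drives variant selection, while the report's two
#' directional columns count band membership.
#'
#' @param ratio_rows One variant's rows from the `ratios` element of an
#'   [call_aei()] result.
#' @param cohort_size Total cohort size (explicit; never inferred from
#'   the data).
#' @param config An [aei_config()] supplying the band bounds.
#' @return A one-row tibble.
#' @export
summarize_variant <- function(ratio_rows, cohort_size,
                              config = aei_config()) {
  stopifnot(nrow(ratio_rows) >= 1)
  n_het <- nrow(ratio_rows)
  n_below <- sum(ratio_rows$linear_ratio < config$ratio_low)
  n_above <- sum(ratio_rows$linear_ratio > config$ratio_high)
  n_imb <- n_below + n_above
  freqs <- aei_frequencies(n_imb, n_het, cohort_size)
  imb <- ratio_rows$linear_ratio[
    ratio_rows$linear_ratio < config$ratio_low |
      ratio_rows$linear_ratio > config$ratio_high]
  if (n_imb > 0) {
    ms <- suppressWarnings(oriented_mean_sem(orient_ratio(imb)))
    kurt <- suppressWarnings(excess_kurtosis(orient_ratio(imb)))
    sek_val <- suppressWarnings(sek(n_imb))
    orient <- max(n_below, n_above) / n_imb
  } else {
    ms <- list(mean = NA_real_, sem = NA_real_)
    kurt <- NA_real_
    sek_val <- NA_real_
    orient <- NA_real_
  }
  tibble(
    chrom = ratio_rows$chrom[1], pos = ratio_rows$pos[1],
    ref = ratio_rows$ref[1], alt = ratio_rows$alt[1],
    rsid = ratio_rows$rsid[1], gene = ratio_rows$gene[1],
    n_het = n_het, n_outlier = sum(ratio_rows$is_outlier),
    n_below = n_below, n_above = n_above, n_imbalanced = n_imb,
    freq_het = freqs$freq_het, freq_cohort = freqs$freq_cohort,
    abs_mean_ratio = ms$mean, sem_ratio = ms$sem,
    kurtosis = kurt, sek = sek_val,
    orientation_fraction = orient,
    is_sex_chrom = sub("^chr", "", ratio_rows$chrom[1]) %in% c("X", "Y")
  )
}

#' Summarize retained variants across the cohort
#'
#' Applies [summarize_variant()] to every retained variant of an
#' [call_aei()] result.
#'
#' @param calls An `aei_calls` object.
#' @param cohort_size Total cohort size.
#' @param exclude_single_hits Keep only variants surviving single-hit
#'   exclusion (`retained_multi`). Default `FALSE`.
#' @return A tibble with one row per retained variant.
#' @export
summarize_cohort <- function(calls, cohort_size,
                             exclude_single_hits = FALSE) {
  stopifnot(inherits(calls, "aei_calls"))
  keep <- if (exclude_single_hits) {
    calls$variants$retained_multi
  } else {
    calls$variants$retained
  }
  kept <- calls$variants[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), rsid = character(), gene = character(),
      n_het = integer(), n_outlier = integer(), n_below = integer(),
      n_above = integer(), n_imbalanced = integer(),
      freq_het = numeric(), freq_cohort = numeric(),
      abs_mean_ratio = numeric(), sem_ratio = numeric(),
      kurtosis = numeric(), sek = numeric(),
      orientation_fraction = numeric(), is_sex_chrom = logical()
    ))
  }
  kept_ids <- variant_id(kept)
  rows <- split(calls$ratios, calls$ratios$variant)[kept_ids]
  out <- dplyr::bind_rows(lapply(rows, summarize_variant,
                                 cohort_size = cohort_size,
                                 config = calls$config))
  dplyr::arrange(out, .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Filter summaries by cohort-level AEI frequency
#'
#' Keeps variants whose AEI frequency in the whole cohort is strictly
#' greater than a threshold (default 10%).
#'
#' @param summaries A tibble from [summarize_cohort()].
#' @param min_freq_cohort Threshold in percent, in \[0, 100\].
#' @return The filtered tibble.
#' @export
frequency_filter <- function(summaries, min_freq_cohort = 10) {
  stopifnot(min_freq_cohort >= 0, min_freq_cohort <= 100)
  summaries[summaries$freq_cohort > min_freq_cohort, , drop = FALSE]
}
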