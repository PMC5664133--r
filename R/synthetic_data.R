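#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The defaults emulate the
#' study conditions the detector targets: 52 samples, marker allele
#' frequency 0.3 under Hardy-Weinberg, mean site depth 80 truncated at
#' the 20x filter minimum, balanced variants at allelic fraction 0.5 with
#' beta-binomial overdispersion rho = 0.01, and cis-regulated variants
#' where the haplotype carrying the repressive regulatory allele
#' contributes 30% of transcripts, the regulatory allele being in full LD
#' (r-squared 1) with the marker's alternative allele.
#'
#' @param n_samples Cohort size. Default 52.
#' @param n_null_variants Number of balanced variants. Default 200.
#' @param n_aei_variants Number of cis-regulated variants. Default 50.
#' @param maf Marker allele frequency (alternative allele). Default 0.3.
#' @param ld_r2 r-squared between the regulatory allele and the marker's
#'   alternative allele, in \[0, 1\]. The regulatory-allele frequency is
#'   tied to `maf`. Default 1.
#' @param mean_depth Mean total read depth per record. Default 80.
#' @param depth_dispersion Negative-binomial size parameter of the depth
#'   spread above the minimum. Default 8.
#' @param null_fraction Allelic fraction of balanced variants. Default 0.5.
#' @param aei_fraction Fraction of transcripts from the haplotype
#'   carrying the repressive regulatory allele, in (0, 1). Default 0.30
#'   (oriented ratio 3/7 ~ 0.43).
#' @param rho Beta-binomial overdispersion (intra-class correlation) of
#'   allele counts, in \[0, 1). Default 0.01.
#' @param min_depth Depth truncation floor, matching the coverage filter.
#'   Default 20.
#' @param low_depth_frac Fraction of records forced below `min_depth` to
#'   exercise the coverage filter. Default 0.
#' @param seed Integer master seed; per-variant substreams are derived by
#'   counter so adding variants never perturbs earlier ones.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 52, n_null_variants = 200,
                       n_aei_variants = 50, maf = 0.3, ld_r2 = 1,
                       mean_depth = 80, depth_dispersion = 8,
                       null_fraction = 0.5, aei_fraction = 0.30,
                       rho = 0.01, min_depth = 20, low_depth_frac = 0,
                       seed = 1L) {
  stopifnot(n_samples >= 1, n_null_variants >= 0, n_aei_variants >= 0,
            maf > 0, maf < 1, ld_r2 >= 0, ld_r2 <= 1,
            mean_depth > min_depth, depth_dispersion > 0,
            null_fraction > 0, null_fraction < 1,
            aei_fraction > 0, aei_fraction < 1,
            rho >= 0, rho < 1, min_depth >= 1,
            low_depth_frac >= 0, low_depth_frac < 1)
  if (n_null_variants + n_aei_variants == 0) {
    stop("sim_config: at least one variant is required", call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, n_null_variants = n_null_variants,
         n_aei_variants = n_aei_variants, maf = maf, ld_r2 = ld_r2,
         mean_depth = mean_depth, depth_dispersion = depth_dispersion,
         null_fraction = null_fraction, aei_fraction = aei_fraction,
         rho = rho, min_depth = min_depth, low_depth_frac = low_depth_frac,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d samples, %d null + %d AEI variants (maf %.2f, r2 %.2f)\n",
    x$n_samples, x$n_null_variants, x$n_aei_variants, x$maf, x$ld_r2))
  cat(sprintf(
    "  depth ~ %g + NB(size %g), aei fraction %.2f, rho %.3f, seed %d\n",
    x$min_depth, x$depth_dispersion, x$aei_fraction, x$rho, x$seed))
  invisible(x)
}

# counter-derived per-variant substream seed, kept inside 32-bit range
variant_seed <- function(seed, i) {
  (as.double(seed) + 1000003 * as.double(i)) %% 2147483647
}

# beta-binomial allele counts; rho = 0 degenerates to binomial
rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) {
    return(stats::rbinom(n, size, prob))
  }
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}

#' Simulate a cohort with known AEI ground truth
#'
#' Generates genotypes per variant under Hardy-Weinberg at the marker
#' frequency, per-record depths from a shifted negative binomial
#' truncated at the coverage minimum, and heterozygous alternative-allele
#' counts from a beta-binomial at the variant's true allelic fraction:
#' 0.5 for null variants; for cis-regulated variants, the configured
#' fraction oriented by the sample's phase. Phase is drawn from a
#' two-locus haplotype model: a biallelic regulatory locus whose
#' repressive allele co-occurs with the marker's alternative allele at a
#' rate set by `ld_r2`. When exactly one haplotype carries the repressive
#' allele, that haplotype contributes `aei_fraction` of transcripts; when
#' both or neither do, expression is balanced.
#'
#' Homozygous samples emit all reads on their single allele. All
#' randomness flows from `config$seed` through counter-derived
#' per-variant substreams, so output is bit-identical under a fixed seed
#' and earlier variants are unchanged when more are added.
#'
#' @param config A [sim_config()].
#' @return A list of class `aei_sim` with elements `counts` (an
#'   [as_count_table()] tibble) and `truth` (a long tibble: `chrom`,
#'   `pos`, `rsid`, `gene`, `sample`, `is_aei`, `true_alt_fraction`,
#'   `phase`, `genotype`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_var <- config$n_null_variants + config$n_aei_variants
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  p <- config$maf
  q <- config$maf  # regulatory-allele frequency tied to the marker's
  D <- sqrt(config$ld_r2) * sqrt(p * (1 - p) * q * (1 - q))
  pr_reg_alt <- min(1, max(0, q + D / p))        # P(repressive | alt hap)
  pr_reg_ref <- min(1, max(0, q - D / (1 - p)))  # P(repressive | ref hap)

  per_variant <- lapply(seq_len(n_var), function(i) {
    withr::with_seed(variant_seed(config$seed, i), {
      n <- config$n_samples
      is_aei <- i > config$n_null_variants
      # two haplotypes per sample; marker allele then linked reg allele
      hap_alt <- matrix(stats::runif(2 * n) < p, ncol = 2)
      reg <- matrix(stats::runif(2 * n), ncol = 2)
      reg <- ifelse(hap_alt, reg < pr_reg_alt, reg < pr_reg_ref)
      if (!is_aei) reg[] <- FALSE
      n_alt <- rowSums(hap_alt)
      genotype <- c("hom_ref", "het", "hom_alt")[n_alt + 1]

      depth <- config$min_depth +
        stats::rnbinom(n, size = config$depth_dispersion,
                       mu = config$mean_depth - config$min_depth)
      if (config$low_depth_frac > 0) {
        low <- stats::runif(n) < config$low_depth_frac
        depth[low] <- pmax(1L, config$min_depth -
                             1L - stats::rbinom(sum(low),
                                                config$min_depth - 2L, 0.5))
      }

      # true fraction of alternative-allele transcripts for het samples
      frac <- rep(config$null_fraction, n)
      phase <- rep("none", n)
      if (is_aei) {
        het <- genotype == "het"
        # for a het, one haplotype carries alt: identify its reg status
        alt_hap_reg <- ifelse(hap_alt[, 1], reg[, 1], reg[, 2])
        ref_hap_reg <- ifelse(hap_alt[, 1], reg[, 2], reg[, 1])
        one_hit <- xor(alt_hap_reg, ref_hap_reg)
        frac[het & one_hit & alt_hap_reg] <- config$aei_fraction
        frac[het & one_hit & ref_hap_reg] <- 1 - config$aei_fraction
        phase[het & one_hit & alt_hap_reg] <- "alt"
        phase[het & one_hit & ref_hap_reg] <- "ref"
        phase[het & alt_hap_reg & ref_hap_reg] <- "both"
      }

      alt_count <- integer(n)
      het <- genotype == "het"
      alt_count[het] <- rbetabinom(sum(het), depth[het], frac[het],
                                   config$rho)
      alt_count[genotype == "hom_alt"] <- depth[genotype == "hom_alt"]
      ref_count <- depth - alt_count

      list(
        counts = tibble(
          chrom = "chr1", pos = 1000L * i, ref = "A", alt = "G",
          rsid = sprintf("rs9%06d", i), qual = 999,
          gene = sprintf("SIMG%04d", i), sample = samples,
          ref_count = as.integer(ref_count),
          alt_count = as.integer(alt_count), genotype = genotype
        ),
        truth = tibble(
          chrom = "chr1", pos = 1000L * i, rsid = sprintf("rs9%06d", i),
          gene = sprintf("SIMG%04d", i), sample = samples,
          is_aei = is_aei, true_alt_fraction = frac, phase = phase,
          genotype = genotype
        )
      )
    })
  })

  counts <- as_count_table(dplyr::bind_rows(lapply(per_variant, `[[`,
                                                   "counts")))
  truth <- dplyr::bind_rows(lapply(per_variant, `[[`, "truth"))
  structure(list(counts = counts, truth = truth, config = config),
            class = "aei_sim")
}

#' @export
print.aei_sim <- function(x, ...) {
  cat(sprintf("<aei_sim> %d samples x %d variants (%d AEI), seed %d\n",
              x$config$n_samples,
              x$config$n_null_variants + x$config$n_aei_variants,
              x$config$n_aei_variants, x$config$seed))
  invisible(x)
}

#' Evaluate detection against simulation truth
#'
#' Compares variant-level detection (the `retained` or `retained_multi`
#' flag of [call_aei()]) against the simulator's `is_aei` labels.
#' Variants present in the truth but absent from the calls (no testable
#' heterozygous sample) count as undetected; calls for variants absent
#' from the truth are an error.
#'
#' @param calls An `aei_calls` object (or its `variants` tibble).
#' @param truth The `truth` tibble of an [simulate_cohort()] result.
#' @param rule Detection rule: `"multi"` (single-hit exclusion, default)
#'   or `"any"` (at least one outlier sample).
#' @return A list with the confusion counts (`tp`, `fp`, `fn`, `tn`),
#'   `sensitivity`, `fpr` and the rule used.
#' @export
truth_eval <- function(calls, truth, rule = c("multi", "any")) {
  rule <- match.arg(rule)
  variants <- if (inherits(calls, "aei_calls")) calls$variants else calls
  truth_var <- dplyr::distinct(truth, .data$chrom, .data$pos, .data$rsid,
                               .data$is_aei)
  extra <- setdiff(variants$rsid, truth_var$rsid)
  if (length(extra) > 0) {
    stop("truth_eval: calls contain variant(s) absent from truth: ",
         paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  }
  detected_ids <- variants$rsid[
    if (rule == "multi") variants$retained_multi else variants$retained]
  detected <- truth_var$rsid %in% detected_ids
  tp <- sum(detected & truth_var$is_aei)
  fp <- sum(detected & !truth_var$is_aei)
  fn <- sum(!detected & truth_var$is_aei)
  tn <- sum(!detected & !truth_var$is_aei)
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    rule = rule
  )
}

#' @rdname truth_eval
#' @param path Output path for the truth table.
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth, path, na = "NA", progress = FALSE)
  invisible(path)
}
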