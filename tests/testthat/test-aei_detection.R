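test_that("selection filters apply the documented thresholds and strictness", {
  cfg <- aei_config()
  base <- make_record(qual = 500, ref_count = 30L, alt_count = 20L)

  expect_true(passes_filters(base, cfg))
  # QUAL threshold is strictly greater-than
  expect_false(passes_filters(make_record(qual = 225), cfg))
  expect_true(passes_filters(make_record(qual = 225.01), cfg))
  # depth and per-allele boundaries: 2 + 18 = 20 reads passes exactly
  expect_true(passes_filters(make_record(ref_count = 2L, alt_count = 18L),
                             cfg))
  expect_false(passes_filters(make_record(ref_count = 2L, alt_count = 17L),
                              cfg))
  # one read on an allele fails no matter the depth
  expect_false(passes_filters(make_record(ref_count = 1L,
                                          alt_count = 100L), cfg))
  # heterozygosity is required
  expect_false(passes_filters(make_record(genotype = "hom_alt",
                                          ref_count = 0L), cfg))
  expect_false(passes_filters(make_record(genotype = "missing"), cfg))
  # dbSNP membership as non-missing rsid, switchable
  norsid <- make_record(rsid = NA_character_)
  expect_false(passes_filters(norsid, cfg))
  expect_true(passes_filters(norsid, aei_config(require_rsid = FALSE)))
  allow <- aei_config(rsid_allowlist = c("rs999"))
  expect_false(passes_filters(base, allow))
})

test_that("allelic ratios are alt/ref with natural-log transform", {
  r <- compute_ratios(make_record(ref_count = 50L, alt_count = 50L))
  expect_equal(r$linear_ratio, 1)
  expect_equal(r$log_ratio, 0)

  r <- compute_ratios(make_record(ref_count = 20L, alt_count = 30L))
  expect_equal(r$linear_ratio, 1.5)
  expect_equal(r$log_ratio, log(1.5))

  # antisymmetry under allele swap
  fwd <- compute_ratios(make_record(ref_count = 30L, alt_count = 20L))
  expect_equal(fwd$log_ratio, -log(1.5))

  expect_error(compute_ratios(make_record(ref_count = 0L)), "zero")
})

test_that("moderate band is strictly outside 0.666-1.5 across a ratio grid", {
  expect_false(moderate_flag(1.5))
  expect_false(moderate_flag(0.666))
  expect_true(moderate_flag(2.0))
  expect_true(moderate_flag(0.5))

  grid <- seq(0.01, 3, by = 0.0037)
  expect_equal(moderate_flag(grid), grid < 0.666 | grid > 1.5)
})

test_that("outlier model stores sample mean/SD and flags strictly outside mean +/- k SD", {
  # constant reference population: bounds collapse, nothing flagged
  m <- fit_outlier_model(rep(0.3, 8))
  expect_equal(m$sd, 0)
  expect_false(any(is_outlier(m, rep(0.3, 8))))

  x <- c(rep(0, 9), 10)
  m <- fit_outlier_model(x)
  expect_equal(m$mean, 1)
  expect_equal(m$sd, sqrt(10), tolerance = 1e-12)  # sample SD 3.1623
  expect_equal(which(is_outlier(m, x)), 10L)

  expect_error(fit_outlier_model(c(1)), "at least 2")
})

test_that("outlier flags are invariant under location shifts of the log ratios", {
  set.seed(61)
  for (i in 1:20) {
    x <- rnorm(40, sd = runif(1, 0.1, 2))
    shift <- runif(1, -5, 5)
    f0 <- is_outlier(fit_outlier_model(x), x)
    f1 <- is_outlier(fit_outlier_model(x + shift), x + shift)
    expect_identical(f0, f1)
  }
})

test_that("call_aei applies the retention and single-hit rescue rules", {
  calls <- call_aei(engineered_cohort())
  v <- calls$variants

  backbone <- v[v$pos <= 1000, ]
  expect_false(any(backbone$retained))

  v11 <- v[v$pos == 1100, ]   # two outlier samples
  expect_equal(v11$n_outlier, 2L)
  expect_true(v11$retained_multi)

  v12 <- v[v$pos == 1200, ]   # single hit, all others balanced
  expect_equal(v12$n_outlier, 1L)
  expect_true(v12$retained)
  expect_false(v12$retained_multi)

  v13 <- v[v$pos == 1300, ]   # single hit rescued by a moderate sample
  expect_equal(v13$n_outlier, 1L)
  expect_true(v13$retained_multi)

  expect_error(call_aei(engineered_cohort()[0, ]), "empty")
})

test_that("call_aei output is invariant to record ordering", {
  tab <- engineered_cohort()
  set.seed(99)
  shuffled <- as_count_table(tab[sample(nrow(tab)), ])
  a <- call_aei(tab)
  b <- call_aei(shuffled)
  expect_equal(a$variants, b$variants)
  expect_equal(a$ratios, b$ratios)
})

test_that("per_variant outlier scope flags within a variant across samples", {
  # one variant, many samples, one extreme sample
  n <- 12
  ref <- matrix(50L, nrow = 2, ncol = n)
  alt <- matrix(c(rep(50L, n), rep(48L, n - 1), 9L), nrow = 2,
                byrow = TRUE)
  ref[2, n] <- 91L
  tab <- counts_from_matrix(ref, alt)
  calls <- call_aei(tab, aei_config(outlier_scope = "per_variant"))
  v <- calls$variants[calls$variants$pos == 200, ]
  expect_equal(v$n_outlier, 1L)
  flagged <- calls$ratios[calls$ratios$is_outlier, ]
  expect_equal(flagged$sample, sprintf("S%02d", n))
})

test_that("sex-chromosome variants are processed but tagged", {
  tab <- dplyr::bind_rows(
    make_record(chrom = "chrX", pos = 10L, rsid = "rsx",
                sample = c("S1", "S2", "S3"),
                ref_count = c(50L, 50L, 10L), alt_count = c(50L, 52L, 90L)),
    make_record(chrom = "chr2", pos = 20L, rsid = "rs2",
                sample = c("S1", "S2", "S3"),
                ref_count = c(50L, 49L, 51L), alt_count = c(50L, 50L, 50L))
  )
  calls <- call_aei(as_count_table(tab))
  expect_equal(calls$variants$is_sex_chrom[calls$variants$chrom == "chrX"],
               TRUE)
  expect_equal(calls$variants$is_sex_chrom[calls$variants$chrom == "chr2"],
               FALSE)
})

test_that("config files round trip through read_aei_config", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# thresholds", "min_qual = 100", "min_depth = 30",
               "require_rsid = false", "outlier_scope = per_variant",
               "k_sd = 3"), path)
  cfg <- read_aei_config(path)
  expect_equal(cfg$min_qual, 100)
  expect_equal(cfg$min_depth, 30)
  expect_false(cfg$require_rsid)
  expect_equal(cfg$outlier_scope, "per_variant")
  expect_equal(cfg$k_sd, 3)

  writeLines(c("min_qual = 100", "mystery = 1"), path)
  expect_warning(read_aei_config(path), "mystery")
})
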