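test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 10, n_null_variants = 15,
                    n_aei_variants = 5, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a$counts), as.data.frame(b$counts))
  expect_identical(a$truth, b$truth)
})

test_that("per-variant substreams keep earlier variants fixed when more are added", {
  small <- simulate_cohort(sim_config(n_samples = 8, n_null_variants = 5,
                                      n_aei_variants = 0, seed = 3))
  big <- simulate_cohort(sim_config(n_samples = 8, n_null_variants = 9,
                                    n_aei_variants = 0, seed = 3))
  first5 <- big$counts[big$counts$pos <= 5000, ]
  expect_identical(as.data.frame(first5), as.data.frame(small$counts))
})

test_that("simulated structure matches the configured cohort", {
  cfg <- sim_config(n_samples = 12, n_null_variants = 20,
                    n_aei_variants = 10, seed = 9)
  sim <- simulate_cohort(cfg)
  # one record per variant per sample
  expect_equal(nrow(sim$counts), 12 * 30)
  expect_equal(nrow(sim$truth), 12 * 30)
  # truth rows align one-to-one with count records
  key <- function(d) paste(d$rsid, d$sample)
  expect_setequal(key(sim$truth), key(sim$counts))
  expect_equal(
    sim$counts$genotype[order(key(sim$counts))],
    sim$truth$genotype[order(key(sim$truth))]
  )
  # depth floor honoured
  expect_true(all(sim$counts$ref_count + sim$counts$alt_count >= 20))
  # homozygous samples put all reads on one allele
  hr <- sim$counts[sim$counts$genotype == "hom_ref", ]
  expect_true(all(hr$alt_count == 0))
  # AEI truth: full-LD repression always sits on the alt haplotype
  aei_het <- sim$truth[sim$truth$is_aei & sim$truth$genotype == "het", ]
  expect_true(all(aei_het$phase == "alt"))
  expect_true(all(aei_het$true_alt_fraction == cfg$aei_fraction))
  null_het <- sim$truth[!sim$truth$is_aei & sim$truth$genotype == "het", ]
  expect_true(all(null_het$true_alt_fraction == 0.5))

  expect_error(sim_config(n_null_variants = 0, n_aei_variants = 0),
               "at least one variant")
})

test_that("deep balanced sequencing concentrates ratios inside the moderate band", {
  cfg <- sim_config(n_samples = 15, n_null_variants = 60,
                    n_aei_variants = 0, mean_depth = 10000,
                    depth_dispersion = 50, rho = 0, seed = 23)
  sim <- simulate_cohort(cfg)
  het <- sim$counts[sim$counts$genotype == "het", ]
  r <- het$alt_count / het$ref_count
  expect_gte(mean(r >= 0.666 & r <= 1.5), 0.99)
})

test_that("an AEI fraction of 0.5 is distributionally null but keeps truth labels", {
  cfg <- sim_config(n_samples = 10, n_null_variants = 5,
                    n_aei_variants = 5, aei_fraction = 0.5, seed = 31)
  sim <- simulate_cohort(cfg)
  expect_true(any(sim$truth$is_aei))
  het <- sim$truth[sim$truth$genotype == "het", ]
  expect_true(all(het$true_alt_fraction == 0.5))
})

test_that("truth_eval counts the confusion matrix against ground truth", {
  sim <- simulate_cohort(sim_config(n_samples = 10, n_null_variants = 6,
                                    n_aei_variants = 4, seed = 41))
  truth_var <- dplyr::distinct(sim$truth, chrom, pos, rsid, is_aei)
  mock_calls <- tibble::tibble(
    rsid = truth_var$rsid,
    retained = truth_var$is_aei,
    retained_multi = truth_var$is_aei
  )
  perfect <- truth_eval(mock_calls, sim$truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fpr, 0)

  nothing <- mock_calls
  nothing$retained_multi <- FALSE
  expect_equal(truth_eval(nothing, sim$truth)$sensitivity, 0)

  # scrambled detection labels match a brute-force recount
  set.seed(2)
  scrambled <- mock_calls
  scrambled$retained_multi <- sample(c(TRUE, FALSE), nrow(scrambled),
                                     replace = TRUE)
  ev <- truth_eval(scrambled, sim$truth)
  brute <- table(detected = scrambled$retained_multi,
                 aei = truth_var$is_aei)
  expect_equal(ev$tp, sum(scrambled$retained_multi & truth_var$is_aei))
  expect_equal(ev$fp, sum(scrambled$retained_multi & !truth_var$is_aei))
  expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, nrow(truth_var))
  expect_equal(ev$sensitivity, ev$tp / sum(truth_var$is_aei))

  bad <- mock_calls
  bad$rsid[1] <- "rs_not_simulated"
  expect_error(truth_eval(bad, sim$truth), "absent from truth")
})

test_that("single-hit exclusion strictly tightens null variant survival", {
  survival <- sapply(1:4, function(s) {
    sim <- simulate_cohort(sim_config(n_samples = 30, n_null_variants = 120,
                                      n_aei_variants = 0, seed = 100 + s))
    calls <- suppressWarnings(call_aei(sim$counts))
    c(any = mean(calls$variants$retained),
      multi = mean(calls$variants$retained_multi))
  })
  expect_true(all(survival["multi", ] < survival["any", ]))
  # every null variant has, in expectation, about one mean +/- 2 SD hit
  # among its ~13 heterozygotes, so the any-hit rule retains most of
  # them; the multi rule must cut that down but stays well above zero
  expect_true(all(survival["multi", ] > 0))
})

test_that("sensitivity grows with effect size and with depth", {
  # Detection rests on an empirical mean +/- 2 SD rule, so sensitivity
  # is a function of how far the cis-effect mode sits from the bulk of
  # each sample's ratios. Averages over fixed seeds; AEI variants are a
  # ~10-25% minority of sites as in real transcriptomes (a majority of
  # regulated sites would inflate the empirical SD itself).
  sens <- function(aei_fraction, depth, seed, n_null, n_aei) {
    sim <- simulate_cohort(sim_config(
      n_samples = 30, n_null_variants = n_null, n_aei_variants = n_aei,
      aei_fraction = aei_fraction, mean_depth = depth, seed = seed))
    calls <- suppressWarnings(call_aei(sim$counts))
    truth_eval(calls, sim$truth)$sensitivity
  }
  by_fraction <- sapply(c(0.5, 0.35, 0.2), function(f) {
    mean(sapply(77:80, sens, aei_fraction = f, depth = 80,
                n_null = 60, n_aei = 25))
  })
  expect_true(all(diff(by_fraction) >= 0))
  expect_gt(by_fraction[3], by_fraction[1])

  by_depth <- sapply(c(30, 80, 200), function(d) {
    mean(sapply(301:305, sens, aei_fraction = 0.40, depth = d,
                n_null = 180, n_aei = 20))
  })
  expect_true(all(diff(by_depth) >= 0))
  expect_gt(by_depth[3], by_depth[1])
})
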