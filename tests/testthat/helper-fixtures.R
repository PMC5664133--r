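# Builders for small, fully specified count tables.

make_record <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                        rsid = "rs1", qual = 500, gene = NA_character_,
                        sample = "S1", ref_count = 30L, alt_count = 20L,
                        genotype = "het") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 rsid = rsid, qual = qual, gene = gene, sample = sample,
                 ref_count = as.integer(ref_count),
                 alt_count = as.integer(alt_count), genotype = genotype)
}

# Build a cohort from matrices of ref/alt counts: rows = variants,
# columns = samples. All records heterozygous, QUAL 500, rsIDs set.
counts_from_matrix <- function(ref_mat, alt_mat, genes = NULL) {
  stopifnot(all(dim(ref_mat) == dim(alt_mat)))
  n_var <- nrow(ref_mat)
  n_samp <- ncol(ref_mat)
  samples <- sprintf("S%02d", seq_len(n_samp))
  if (is.null(genes)) genes <- rep(NA_character_, n_var)
  recs <- lapply(seq_len(n_var), function(i) {
    make_record(pos = 100L * i, rsid = sprintf("rs%d", i), gene = genes[i],
                sample = samples, ref_count = ref_mat[i, ],
                alt_count = alt_mat[i, ])
  })
  aeiscan::as_count_table(dplyr::bind_rows(recs))
}

# Three-sample cohort engineered so that, under the per-sample
# mean +/- 2 SD rule, variant v11 has two outlier samples, v12 exactly
# one with all other samples balanced, and v13 one outlier plus one
# moderately imbalanced non-outlier sample (arithmetic checked by hand).
engineered_cohort <- function() {
  n_backbone <- 10
  ref <- matrix(50L, nrow = n_backbone + 3, ncol = 3)
  alt <- matrix(50L, nrow = n_backbone + 3, ncol = 3)
  # v11: samples 1 and 2 extreme
  ref[11, ] <- c(10L, 12L, 50L)
  alt[11, ] <- c(90L, 88L, 50L)
  # v12: only sample 3 extreme, others exactly balanced
  ref[12, ] <- c(50L, 50L, 90L)
  alt[12, ] <- c(50L, 50L, 10L)
  # v13: sample 1 extreme, sample 2 moderate (ratio 64/36 = 1.78)
  ref[13, ] <- c(10L, 36L, 50L)
  alt[13, ] <- c(90L, 64L, 50L)
  counts_from_matrix(ref, alt)
}
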