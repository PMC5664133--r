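#' Run the full AEI scan
#'
#' Wires the stages end to end: read the input (VCF or count-table TSV),
#' apply the selection filters, compute ratios and outlier flags, call
#' AEI per variant, summarize retained variants across the cohort,
#' optionally restrict to a gene panel and remove blacklisted regions,
#' and apply the cohort-frequency filter. When `out_dir` is given, a
#' tab-separated report (`aei_summary.tsv`) and a run manifest
#' (`manifest.json`) are written; the report is byte-identical across
#' runs on identical inputs and configuration.
#'
#' @param input A count table, or a path to a VCF (`.vcf`/`.vcf.gz`) or
#'   count-table TSV.
#' @param cohort_size Total cohort size used for the cohort frequency
#'   (explicit; never inferred from the input).
#' @param config An [aei_config()].
#' @param panel Optional gene panel: a path or a [load_panel()] tibble.
#' @param blacklist Optional region blacklist: a BED path or a
#'   [load_blacklist()] `GRanges`.
#' @param min_cohort_freq Cohort AEI frequency threshold in percent
#'   (strictly-greater-than; default 10). Use 0 to keep everything with
#'   `freq_cohort > 0`, or `NULL` to skip the filter.
#' @param exclude_single_hits Drop variants with a single outlier sample
#'   and no further moderately imbalanced sample. Default `FALSE`.
#' @param out_dir Optional output directory.
#' @return A list of class `aei_scan` with `summaries`, `calls`, and the
#'   paths written (if any).
#' @export
run_scan <- function(input, cohort_size, config = aei_config(),
                     panel = NULL, blacklist = NULL,
                     min_cohort_freq = 10, exclude_single_hits = FALSE,
                     out_dir = NULL) {
  input_path <- NULL
  if (is.character(input)) {
    input_path <- input
    table <- if (grepl("\\.vcf(\\.gz)?$", input)) {
      read_vcf(input)
    } else {
      read_count_table(input)
    }
  } else {
    table <- as_count_table(input)
  }

  calls <- call_aei(table, config)
  summaries <- summarize_cohort(calls, cohort_size = cohort_size,
                                exclude_single_hits = exclude_single_hits)
  if (!is.null(panel)) {
    if (is.character(panel)) panel <- load_panel(panel)
    summaries <- filter_by_panel(summaries, panel)
  }
  if (!is.null(blacklist)) {
    summaries <- filter_by_blacklist(summaries, blacklist)
  }
  if (!is.null(min_cohort_freq)) {
    summaries <- frequency_filter(summaries, min_cohort_freq)
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    summary_path <- file.path(out_dir, "aei_summary.tsv")
    write_summary_table(summaries, summary_path)
    manifest_path <- write_manifest(
      out_dir, command = "scan",
      config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
      params = list(cohort_size = cohort_size,
                    min_cohort_freq = min_cohort_freq,
                    exclude_single_hits = exclude_single_hits),
      inputs = input_path
    )
    paths <- c(summary = summary_path, manifest = manifest_path)
  }
  structure(list(summaries = summaries, calls = calls, paths = paths),
            class = "aei_scan")
}

#' @export
print.aei_scan <- function(x, ...) {
  cat(sprintf("<aei_scan> %d variant(s) in final report\n",
              nrow(x$summaries)))
  print(x$calls)
  invisible(x)
}

#' Run the cohort simulator and write its outputs
#'
#' Generates a synthetic cohort and writes the count table
#' (`sim_counts.tsv`), a VCF (`sim.vcf.gz`), the ground truth
#' (`sim_truth.tsv`), and a run manifest to `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return The [simulate_cohort()] result, with a `paths` element added.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  sim <- simulate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(out_dir, "sim_counts.tsv")
  vcf_path <- file.path(out_dir, "sim.vcf.gz")
  truth_path <- file.path(out_dir, "sim_truth.tsv")
  write_count_table(sim$counts, counts_path)
  write_vcf(sim$counts, vcf_path)
  write_truth_table(sim$truth, truth_path)
  manifest_path <- write_manifest(out_dir, command = "simulate",
                                  config = unclass(config), params = NULL,
                                  inputs = NULL, seed = config$seed)
  sim$paths <- c(counts = counts_path, vcf = vcf_path, truth = truth_path,
                 manifest = manifest_path)
  sim
}

#' Run the pyrosequencing comparison and write its output
#'
#' @param input Path to a replicate-measurement TSV (see
#'   [read_pyro_measurements()]) or an equivalent tibble.
#' @param out_dir Output directory for `pyro_results.tsv` and the
#'   manifest.
#' @param band Balance band in percent, default `c(40, 60)`.
#' @return The [pyro_validate()] tibble, invisibly, with paths attached
#'   as attribute `"paths"`.
#' @export
run_pyro <- function(input, out_dir, band = c(40, 60)) {
  input_path <- NULL
  if (is.character(input)) {
    input_path <- input
    measurements <- read_pyro_measurements(input)
  } else {
    measurements <- input
  }
  results <- pyro_validate(measurements, band = band)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results_path <- file.path(out_dir, "pyro_results.tsv")
  write_pyro_results(results, results_path)
  manifest_path <- write_manifest(out_dir, command = "pyro",
                                  config = list(band = band), params = NULL,
                                  inputs = input_path)
  attr(results, "paths") <- c(results = results_path,
                              manifest = manifest_path)
  invisible(results)
}

# every output directory gets exactly one manifest describing the run
write_manifest <- function(out_dir, command, config, params = NULL,
                           inputs = NULL, seed = NULL) {
  manifest <- list(
    tool = "aeiscan",
    version = as.character(utils::packageVersion("aeiscan")),
    command = command,
    created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = seed,
    config = config,
    params = params
  )
  if (!is.null(inputs)) {
    manifest$inputs <- lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  }
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  path
}
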