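#' Load a disease-gene panel
#'
#' Reads a RetNet-style plain-text panel: one gene symbol per line, with
#' an optional tab-separated second column carrying an inheritance
#' annotation (e.g. `AD` for autosomal dominant). Symbols are upper-cased
#' and deduplicated (with a warning).
#'
#' @param path Path to the panel file.
#' @return A tibble of class `gene_panel` with columns `gene`,
#'   `inheritance` (`NA` when absent) and `dominant` (logical,
#'   `inheritance == "AD"`).
#' @export
load_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    stop("gene panel file is empty: ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  gene <- toupper(vapply(parts, `[`, "", 1))
  inheritance <- toupper(vapply(parts, function(p) {
    if (length(p) >= 2) p[2] else NA_character_
  }, ""))
  dup <- duplicated(gene)
  if (any(dup)) {
    warning("gene panel: collapsing duplicate symbol(s): ",
            paste(unique(gene[dup]), collapse = ", "), call. = FALSE)
  }
  panel <- tibble(gene = gene, inheritance = inheritance)[!dup, ]
  panel$dominant <- !is.na(panel$inheritance) & panel$inheritance == "AD"
  class(panel) <- c("gene_panel", class(panel))
  panel
}

#' Restrict summaries to a gene panel
#'
#' Keeps summary rows whose gene symbol (case-insensitive) is in the
#' panel, annotating the dominant-inheritance flag. Rows lacking a gene
#' annotation are dropped with a warning.
#'
#' @param summaries A tibble from [summarize_cohort()] with a `gene`
#'   column.
#' @param panel A [load_panel()] tibble.
#' @return The filtered tibble with a `dominant` column appended.
#' @export
filter_by_panel <- function(summaries, panel) {
  no_gene <- is.na(summaries$gene)
  if (any(no_gene)) {
    warning("filter_by_panel: dropping ", sum(no_gene),
            " summary row(s) without gene annotation", call. = FALSE)
    summaries <- summaries[!no_gene, , drop = FALSE]
  }
  idx <- match(toupper(summaries$gene), panel$gene)
  out <- summaries[!is.na(idx), , drop = FALSE]
  out$dominant <- panel$dominant[idx[!is.na(idx)]]
  out
}

#' Load a region blacklist from BED
#'
#' Reads a BED3(+label) file of mapping-conflictive regions via
#' \pkg{rtracklayer}, after a light pre-scan that reports malformed lines
#' by number. BED intervals are 0-based half-open; a variant at 1-based
#' position `pos` falls in `[start, end)` when `pos - 1` does.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] of blacklist intervals.
#' @export
load_blacklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  check <- which(nzchar(trimws(lines)) &
                   !grepl("^(track|browser|#)", lines))
  for (i in check) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 3 || is.na(start) || is.na(end) || start >= end) {
      stop("malformed BED line ", i, " in ", path, ": '", lines[i], "'",
           call. = FALSE)
    }
  }
  rtracklayer::import(path, format = "BED")
}

#' Remove summaries falling in blacklisted regions
#'
#' Drops summary rows whose variant position overlaps any blacklist
#' interval. Chromosome names must use the same convention in both
#' inputs.
#'
#' @param summaries A tibble with `chrom` and `pos` columns.
#' @param blacklist A BED file path or a `GRanges` from
#'   [load_blacklist()].
#' @return The filtered tibble.
#' @export
filter_by_blacklist <- function(summaries, blacklist) {
  if (is.character(blacklist)) {
    blacklist <- load_blacklist(blacklist)
  }
  if (nrow(summaries) == 0 || length(blacklist) == 0) {
    return(summaries)
  }
  pts <- GenomicRanges::GRanges(
    seqnames = summaries$chrom,
    ranges = IRanges::IRanges(start = summaries$pos, width = 1)
  )
  # disjoint chromosome sets between data and blacklist are expected
  hit <- suppressWarnings(IRanges::overlapsAny(pts, blacklist))
  summaries[!hit, , drop = FALSE]
}
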