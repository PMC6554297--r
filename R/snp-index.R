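#' Compute per-bulk SNP indices and delta(SNP index)
#'
#' The SNP index of a bulk at a SNP is the fraction of its reads carrying
#' the donor allele (here polarized so index 1 means pure donor/high-parent
#' genome). delta is index_high - index_low; it is ~0 genome-wide and
#' departs from 0 near a locus under divergent selection between the bulks.
#' Records with zero depth in either bulk get `NA` indices (undefined) and
#' are excluded by downstream filters and window statistics.
#'
#' @param counts Tibble of per-SNP count records with columns `chrom`,
#'   `pos`, `donor_count_high`, `depth_high`, `donor_count_low`,
#'   `depth_low` (e.g. from [simulate_bulk_reads()] or [read_counts_tsv()]).
#' @return The input with added columns `index_high`, `index_low`, `delta`.
#' @examples
#' compute_snp_index(tibble::tibble(chrom = "chr6", pos = 1e6,
#'   donor_count_high = 22, depth_high = 29,
#'   donor_count_low = 7, depth_low = 29))
#' @export
compute_snp_index <- function(counts) {
  assert_count_columns(counts, "compute_snp_index")
  bad <- counts$donor_count_high > counts$depth_high |
    counts$donor_count_low > counts$depth_low |
    counts$donor_count_high < 0 | counts$donor_count_low < 0
  if (any(bad)) {
    abort(paste0("compute_snp_index: donor count outside [0, depth] at row(s) ",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  out <- counts |>
    dplyr::mutate(
      index_high = ifelse(.data$depth_high >= 1,
                          .data$donor_count_high / .data$depth_high, NA_real_),
      index_low = ifelse(.data$depth_low >= 1,
                         .data$donor_count_low / .data$depth_low, NA_real_),
      delta = .data$index_high - .data$index_low
    )
  n_undef <- sum(is.na(out$delta))
  if (n_undef > 0) {
    inform(paste0("compute_snp_index: ", n_undef,
                  " record(s) with zero depth flagged undefined"))
  }
  out
}

#' Keep SNPs with sufficient read support in both bulks
#'
#' Mirrors the high-confidence SNP selection of a QTL-seq scan: by default
#' a record is kept only when read depth is at least `min_depth` in *both*
#' bulks (boundary inclusive), the conservative rule that keeps the two
#' indices comparable. `rule = "either"` requires one bulk, `rule = "sum"`
#' applies the threshold to the summed depth.
#'
#' @param records Count or index tibble with `depth_high` and `depth_low`.
#' @param min_depth Minimum read depth (default 29).
#' @param rule How the threshold combines the two bulks (default `"both"`).
#' @return Filtered tibble, input order preserved; the number kept and
#'   dropped is reported via a message.
#' @export
filter_by_depth <- function(records, min_depth = 29,
                            rule = c("both", "either", "sum")) {
  rule <- match.arg(rule)
  if (min_depth < 1) abort("filter_by_depth: min_depth must be >= 1")
  keep <- switch(rule,
                 both = records$depth_high >= min_depth &
                   records$depth_low >= min_depth,
                 either = records$depth_high >= min_depth |
                   records$depth_low >= min_depth,
                 sum = records$depth_high + records$depth_low >= min_depth)
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  inform(paste0("filter_by_depth: kept ", nrow(out), "/", nrow(records),
                " record(s) with depth >= ", min_depth, " (rule: ", rule,
                ")"))
  out
}

#' Remove SNPs with a low index in both bulks
#'
#' SNPs whose index is below the threshold in *both* bulks are likely
#' spurious calls from sequencing or alignment error (a real segregating
#' SNP should show the donor allele in at least one bulk). Removal uses
#' strict inequality: a record at exactly the threshold is kept.
#'
#' @param records Index tibble from [compute_snp_index()].
#' @param threshold Low-index threshold in (0, 1); default 0.3.
#' @return Filtered tibble; records with undefined (`NA`) indices are also
#'   dropped here.
#' @export
filter_low_index_both <- function(records, threshold = 0.3) {
  if (threshold <= 0 || threshold >= 1) {
    abort("filter_low_index_both: threshold must be in (0, 1)")
  }
  if (!all(c("index_high", "index_low") %in% names(records))) {
    abort("filter_low_index_both: run compute_snp_index() first")
  }
  defined <- !is.na(records$index_high) & !is.na(records$index_low)
  low_both <- defined & records$index_high < threshold &
    records$index_low < threshold
  out <- records[defined & !low_both, , drop = FALSE]
  inform(paste0("filter_low_index_both: removed ", sum(low_both),
                " low-index record(s), ", sum(!defined),
                " undefined; kept ", nrow(out)))
  out
}
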