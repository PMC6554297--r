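#' Run a full delta(SNP index) genome scan
#'
#' Chains the whole BSA-seq statistical pipeline on a per-SNP count table:
#' SNP indices, depth and low-index filters, Monte-Carlo null distribution
#' and per-SNP empirical p-values, sliding-window smoothing, null
#' confidence bounds, and QTL-region calling.
#'
#' @param counts Per-SNP count tibble (see [compute_snp_index()] for the
#'   required columns), e.g. from [simulate_bsa_experiment()],
#'   [read_counts_tsv()] or [read_counts_vcf()].
#' @param null Optional pre-built [null_delta_distribution()] object (reuse
#'   it across scans to avoid resimulating); when `NULL`, a null sample is
#'   simulated for every depth observed after filtering.
#' @param min_depth Per-bulk depth filter (default 29).
#' @param low_index_threshold Both-bulk low-index filter (default 0.3).
#' @inheritParams sliding_windows
#' @inheritParams call_regions
#' @param bulk_size,n_sims,seed Null-simulation parameters, used only when
#'   `null` is `NULL`.
#' @return Object of class `bsa_scan`: list with `snps` (filtered index
#'   table with `p`), `windows`, `ci`, `regions` and `params`.
#' @examples
#' map <- build_genome_map(c(chr6 = 31e6), snp_spacing = 250e3)
#' sim <- simulate_bsa_experiment(map,
#'   qtls = data.frame(chrom = "chr6", pos = 6.5e6, additive_effect = 1),
#'   heritability = 0.8, seed = 7)
#' scan <- run_bsa_scan(sim$counts, min_depth = 10, n_sims = 5000)
#' scan$regions
#' @export
run_bsa_scan <- function(counts, null = NULL, min_depth = 29,
                         low_index_threshold = 0.3,
                         window_bp = 2e6, step_bp = 1e4, min_snps = 3,
                         chrom_lengths = NULL,
                         level = 0.95, p_threshold = 0.05,
                         max_gap_windows = 2,
                         donor_high = "high-parent",
                         donor_low = "low-parent",
                         bulk_size = 20, n_sims = 1e5, seed = 1) {
  snps <- counts |>
    compute_snp_index() |>
    filter_by_depth(min_depth = min_depth) |>
    filter_low_index_both(threshold = low_index_threshold)
  if (nrow(snps) == 0) {
    abort("run_bsa_scan: no SNPs survive filtering")
  }
  if (is.null(null)) {
    depths <- sort(unique(round((snps$depth_high + snps$depth_low) / 2)))
    null <- null_delta_distribution(depths, bulk_size = bulk_size,
                                    n_sims = n_sims, seed = seed)
  }
  snps <- add_empirical_p(snps, null)
  windows <- sliding_windows(snps, window_bp = window_bp, step_bp = step_bp,
                             min_snps = min_snps,
                             chrom_lengths = chrom_lengths)
  ci <- ci_table(null, levels = sort(unique(c(0.95, 0.99, level))))
  regions <- call_regions(windows, ci, level = level,
                          p_threshold = p_threshold,
                          max_gap_windows = max_gap_windows,
                          donor_high = donor_high, donor_low = donor_low)
  structure(list(snps = snps, windows = windows, ci = ci, regions = regions,
                 params = list(min_depth = min_depth,
                               low_index_threshold = low_index_threshold,
                               window_bp = window_bp, step_bp = step_bp,
                               min_snps = min_snps, level = level,
                               p_threshold = p_threshold,
                               max_gap_windows = max_gap_windows,
                               bulk_size = null$bulk_size,
                               n_sims = null$n_sims, seed = null$seed)),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  p <- x$params
  cat("delta(SNP index) genome scan\n")
  cat("  SNPs after filters:", nrow(x$snps),
      paste0("(min depth ", p$min_depth, ", low-index < ",
             p$low_index_threshold, " in both bulks removed)"), "\n")
  cat("  windows:", nrow(x$windows),
      paste0("(", p$window_bp / 1e6, " Mb / ", p$step_bp / 1e3, " kb step)"),
      "\n")
  cat("  regions called at level", p$level, ":", nrow(x$regions), "\n")
  if (nrow(x$regions) > 0) print(x$regions)
  invisible(x)
}
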