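#' Sliding-window means of SNP indices and delta
#'
#' Smooths the per-SNP statistics over a genome-wide sliding window
#' (default 2 Mb windows advanced in 10 kb steps). Windows start at
#' position 1, 1 + step, ... on each chromosome, keeping only windows that
#' fit entirely on the chromosome so all windows have the same true width;
#' a SNP belongs to the closed interval `[start, start + window_bp - 1]`
#' (1-based, inclusive).
#' Means are unweighted arithmetic means over member SNPs; windows holding
#' fewer than `min_snps` defined SNPs emit `NA` means. Records with
#' undefined indices (zero depth) are ignored.
#'
#' @param records Index tibble from [compute_snp_index()], sorted by
#'   position within chromosome; a `p` column (see [add_empirical_p()]) is
#'   averaged into `mean_p` when present.
#' @param window_bp Window size in bp (default 2e6).
#' @param step_bp Step between window starts in bp (default 1e4); must not
#'   exceed `window_bp`.
#' @param min_snps Minimum SNPs for a window to report means (default 3;
#'   guards against single-SNP spikes).
#' @param chrom_lengths Optional named chromosome lengths; windows are laid
#'   out up to the chromosome end (default: up to the last SNP).
#' @return Tibble with `chrom`, `window_start`, `window_end`, `n_snps`,
#'   `mean_index_high`, `mean_index_low`, `mean_delta`, `mean_depth` and,
#'   when input had `p`, `mean_p`.
#' @export
sliding_windows <- function(records, window_bp = 2e6, step_bp = 1e4,
                            min_snps = 3, chrom_lengths = NULL) {
  if (window_bp < step_bp) {
    abort("sliding_windows: window_bp must be >= step_bp")
  }
  assert_sorted_records(records, "sliding_windows")
  if (!all(c("index_high", "index_low", "delta") %in% names(records))) {
    abort("sliding_windows: run compute_snp_index() first")
  }
  has_p <- "p" %in% names(records)
  recs <- records[!is.na(records$delta), , drop = FALSE]

  one_chrom <- function(r, nm) {
    extent <- if (!is.null(chrom_lengths) && nm %in% names(chrom_lengths)) {
      chrom_lengths[[nm]]
    } else {
      max(r$pos)
    }
    # full-width windows only: a trailing partial window would hold few
    # SNPs and emit a noisy, incomparable mean
    starts <- seq(1, max(1, extent - window_bp + 1), by = step_bp)
    ends <- starts + window_bp - 1
    # windowed sums via prefix sums over the position-sorted records
    csum <- function(v) cumsum(c(0, v))
    i1 <- findInterval(starts - 1, r$pos)
    i2 <- findInterval(ends, r$pos)
    n <- i2 - i1
    wmean <- function(v) {
      cs <- csum(v)
      m <- (cs[i2 + 1] - cs[i1 + 1]) / n
      m[n < min_snps] <- NA_real_
      m
    }
    out <- tibble(
      chrom = nm, window_start = starts, window_end = ends, n_snps = n,
      mean_index_high = wmean(r$index_high),
      mean_index_low = wmean(r$index_low),
      mean_delta = wmean(r$delta),
      mean_depth = wmean((r$depth_high + r$depth_low) / 2)
    )
    if (has_p) out$mean_p <- wmean(r$p)
    out
  }

  recs |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_split() |>
    purrr::map(\(r) one_chrom(r, r$chrom[1])) |>
    purrr::list_rbind()
}
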