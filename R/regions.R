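#' Construct a QTL-region summary table
#'
#' Builds the region summary used throughout the package (and written as
#' the region TSV): one row per candidate region with its physical bounds,
#' interval length in Mb, the range of windowed delta values, the
#' confidence level attained and the parent donating the trait-raising
#' allele.
#'
#' @param chrom Chromosome name(s).
#' @param start,end Region bounds in bp (1-based, inclusive); `start < end`.
#' @param delta_min,delta_max Range of window mean delta over the region.
#' @param level Confidence level at which the region was called.
#' @param donor Parent whose allele raises the trait across the region.
#' @return Tibble with columns `chrom`, `start`, `end`, `interval_mb`,
#'   `delta_min`, `delta_max`, `level`, `donor`.
#' @examples
#' qtl_regions("chr6", 5590000, 7770000)
#' @export
qtl_regions <- function(chrom, start, end, delta_min = NA_real_,
                        delta_max = NA_real_, level = NA_real_,
                        donor = NA_character_) {
  if (any(start >= end)) abort("qtl_regions: start must be < end")
  if (any(start < 1)) abort("qtl_regions: start must be >= 1")
  tibble(chrom = chrom, start = start, end = end,
         interval_mb = (end - start) / 1e6,
         delta_min = delta_min, delta_max = delta_max,
         level = level, donor = donor)
}

#' Call QTL regions from windowed statistics
#'
#' A window is significant when its |mean delta| exceeds the null
#' confidence bound for its read depth at the requested level *and* its
#' mean empirical p-value is below `p_threshold`. Runs of significant
#' windows of the same delta sign merge into one region whose bounds are
#' the outermost window bounds. Two significant windows join the same run
#' when their genomic extents overlap (with a window/step ratio of w, any
#' two windows fewer than w steps apart share sequence) or when at most
#' `max_gap_windows` further window positions separate them; for
#' non-overlapping tiling windows this reduces to "gaps of at most
#' `max_gap_windows` non-significant windows". The donor parent is
#' assigned from the sign of delta: positive delta means the high bulk is
#' enriched for the donor allele.
#'
#' @param windows Window tibble from [sliding_windows()] (must carry
#'   `mean_p`, see [add_empirical_p()]).
#' @param ci CI table from [ci_table()].
#' @param level Confidence level to call at (must be present in `ci`).
#' @param p_threshold Window mean p-value cutoff (default 0.05).
#' @param max_gap_windows Non-significant windows tolerated inside a region
#'   (default 2); a sign change always splits.
#' @param donor_high,donor_low Parent names reported as donor for positive
#'   and negative delta regions.
#' @return A [qtl_regions()] tibble with an extra `n_windows` column; zero
#'   rows when nothing is significant.
#' @export
call_regions <- function(windows, ci, level = 0.95, p_threshold = 0.05,
                         max_gap_windows = 2,
                         donor_high = "high-parent", donor_low = "low-parent") {
  if (!"mean_p" %in% names(windows)) {
    abort("call_regions: windows must carry mean_p (see add_empirical_p)")
  }
  empty <- qtl_regions("x", 1, 2)[0, ] |> dplyr::mutate(n_windows = integer())
  if (nrow(windows) == 0) return(empty)
  ci_lev <- ci[abs(ci$level - level) < 1e-9, , drop = FALSE]
  if (nrow(ci_lev) == 0) {
    abort(paste0("call_regions: level ", level, " not present in ci table"))
  }

  one_chrom <- function(w) {
    ok <- !is.na(w$mean_delta) & !is.na(w$mean_p)
    bound <- rep(NA_real_, nrow(w))
    bound[ok] <- ci_lev$upper[match(nearest_match(round(w$mean_depth[ok]),
                                                  ci_lev$depth),
                                    ci_lev$depth)]
    sig <- ok & abs(w$mean_delta) > bound & w$mean_p < p_threshold
    if (!any(sig)) return(NULL)
    step <- if (nrow(w) > 1) min(diff(w$window_start)) else 1
    wsize <- w$window_end[1] - w$window_start[1] + 1
    ratio <- max(1, round(wsize / step))
    idx <- which(sig)
    sgn <- sign(w$mean_delta[idx])
    new_run <- c(TRUE, diff(idx) > max_gap_windows + ratio |
                   sgn[-1] != sgn[-length(sgn)])
    run <- cumsum(new_run)
    purrr::map(split(idx, run), function(i) {
      qtl_regions(
        chrom = w$chrom[1],
        start = min(w$window_start[i]),
        end = max(w$window_end[i]),
        delta_min = min(w$mean_delta[i]),
        delta_max = max(w$mean_delta[i]),
        level = level,
        donor = if (sign(w$mean_delta[i[1]]) > 0) donor_high else donor_low
      ) |>
        dplyr::mutate(n_windows = length(i))
    }) |> purrr::list_rbind()
  }

  out <- windows |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_split() |>
    purrr::map(one_chrom) |>
    purrr::list_rbind()
  if (is.null(out) || nrow(out) == 0) empty else out
}
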