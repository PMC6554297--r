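# shared fixtures, all generated in code

# index records on one chromosome with given positions and deltas; indices
# chosen symmetric about 0.5 so delta = 2 * (index_high - 0.5)
toy_index_records <- function(pos, delta, chrom = "chr1", depth = 30) {
  tibble::tibble(
    chrom = chrom, pos = pos,
    donor_count_high = NA_real_, depth_high = depth,
    donor_count_low = NA_real_, depth_low = depth,
    index_high = 0.5 + delta / 2, index_low = 0.5 - delta / 2,
    delta = delta
  )
}

random_counts <- function(n, seed, chrom = "chr1", depth_mean = 22) {
  withr::with_seed(seed, {
    depth_h <- stats::rpois(n, depth_mean)
    depth_l <- stats::rpois(n, depth_mean)
    tibble::tibble(
      chrom = chrom, pos = sort(sample.int(1e7, n)),
      donor_count_high = stats::rbinom(n, depth_h, 0.5), depth_high = depth_h,
      donor_count_low = stats::rbinom(n, depth_l, 0.5), depth_low = depth_l
    )
  })
}

# brute-force window oracle: rescan all SNPs for every window
brute_force_windows <- function(records, window_bp, step_bp, min_snps,
                                extent = max(records$pos)) {
  records <- records[!is.na(records$delta), ]
  starts <- seq(1, max(1, extent - window_bp + 1), by = step_bp)
  rows <- lapply(starts, function(s) {
    e <- s + window_bp - 1
    in_w <- records$pos >= s & records$pos <= e
    n <- sum(in_w)
    m <- function(v) if (n >= min_snps) mean(v[in_w]) else NA_real_
    tibble::tibble(
      chrom = records$chrom[1], window_start = s, window_end = e, n_snps = n,
      mean_index_high = m(records$index_high),
      mean_index_low = m(records$index_low),
      mean_delta = m(records$delta),
      mean_depth = m((records$depth_high + records$depth_low) / 2)
    )
  })
  dplyr::bind_rows(rows)
}
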