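#' Monte-Carlo null distribution of delta(SNP index)
#'
#' Simulates delta under the no-QTL null for given read depths. Each
#' replicate draws, independently per bulk, `bulk_size` F2 dosage fractions
#' from {0, 1/2, 1} with probabilities (1/4, 1/2, 1/4), takes the bulk
#' allele frequency as their mean, then samples a Binomial(depth, p) donor
#' read count; delta is index_high - index_low. (The sum of `bulk_size`
#' F2 dosages is Binomial(2 * bulk_size, 1/2), which is how the sampler is
#' vectorized.) Under this null, Var(delta) = 2 (1/(8 B) + E[p(1-p)]/d)
#' for bulk size B and depth d.
#'
#' @param depths Integer vector of read depths to simulate (per bulk).
#' @param bulk_size Individuals per bulk (default 20).
#' @param n_sims Replicates per depth (default 100000).
#' @param seed Integer seed; each depth uses an independent substream
#'   derived from it, so the sample for a depth does not depend on which
#'   other depths are requested.
#' @param low_index_filter Optional threshold: when set (e.g. 0.3), null
#'   replicates whose two indices both fall below it are discarded,
#'   mimicking the low-index data filter inside the null (off by default;
#'   the filtered sample is then shorter than `n_sims`).
#' @return Object of class `bsa_null`: a list with `samples` (named list of
#'   numeric delta vectors, one per depth), `depths`, `bulk_size`,
#'   `n_sims`, `seed`.
#' @examples
#' null <- null_delta_distribution(29, bulk_size = 20, n_sims = 2e4, seed = 1)
#' sd(null$samples[["29"]])
#' @export
null_delta_distribution <- function(depths, bulk_size = 20, n_sims = 1e5,
                                    seed = 1, low_index_filter = NULL) {
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1)) abort("null_delta_distribution: depths must be >= 1")
  if (bulk_size < 1) abort("null_delta_distribution: bulk_size must be >= 1")
  samples <- lapply(depths, function(d) {
    withr::with_seed(derive_seed(seed, "null", extra = d), {
      draw <- function() {
        p <- stats::rbinom(n_sims, 2L * bulk_size, 0.5) / (2 * bulk_size)
        stats::rbinom(n_sims, d, p) / d
      }
      hi <- draw()
      lo <- draw()
      if (!is.null(low_index_filter)) {
        keep <- !(hi < low_index_filter & lo < low_index_filter)
        hi <- hi[keep]
        lo <- lo[keep]
      }
      hi - lo
    })
  })
  names(samples) <- as.character(depths)
  structure(list(samples = samples, depths = depths, bulk_size = bulk_size,
                 n_sims = n_sims, seed = seed),
            class = "bsa_null")
}

#' @export
print.bsa_null <- function(x, ...) {
  cat("Null delta(SNP index) samples: bulk size", x$bulk_size, ",",
      x$n_sims, "replicates at depth(s)",
      paste(x$depths, collapse = ", "), "\n")
  invisible(x)
}

nearest_match <- function(x, grid) {
  vapply(x, function(v) grid[which.min(abs(grid - v))], numeric(1))
}

#' Confidence-interval table for delta(SNP index) under the null
#'
#' Two-sided empirical bounds of the null delta distribution per depth: the
#' upper bound at level L is the 1 - (1-L)/2 quantile (e.g. the 97.5th
#' percentile at 95%), the lower bound its mirror. Windows or SNPs whose
#' |delta| exceeds the bound at their depth are candidate QTL signals.
#'
#' @param depths Depth vector, or an existing `bsa_null` object to reuse.
#' @param levels Confidence levels (default 0.95 and 0.99).
#' @param two_sided Use the two-sided convention (default); with
#'   `two_sided = FALSE` the upper bound at level L is the L quantile
#'   itself (and the lower bound the 1 - L quantile).
#' @inheritParams null_delta_distribution
#' @return Tibble of class `bsa_ci` with columns `depth`, `level`, `lower`,
#'   `upper`; attributes carry `bulk_size`, `n_sims`, `seed`.
#' @examples
#' ci_table(29, n_sims = 2e4, seed = 1)
#' @export
ci_table <- function(depths, levels = c(0.95, 0.99), bulk_size = 20,
                     n_sims = 1e5, seed = 1, two_sided = TRUE) {
  null <- if (inherits(depths, "bsa_null")) depths else
    null_delta_distribution(depths, bulk_size = bulk_size, n_sims = n_sims,
                            seed = seed)
  tail_p <- function(L) if (two_sided) (1 - L) / 2 else 1 - L
  rows <- purrr::map(null$depths, function(d) {
    s <- null$samples[[as.character(d)]]
    purrr::map(levels, function(L) {
      q <- stats::quantile(s, c(tail_p(L), 1 - tail_p(L)), names = FALSE)
      tibble(depth = d, level = L, lower = q[1], upper = q[2])
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(rows,
            bulk_size = null$bulk_size, n_sims = null$n_sims,
            seed = null$seed,
            class = c("bsa_ci", class(tibble())))
}

#' Two-sided empirical p-value against a null delta sample
#'
#' p = (1 + #\{|null delta| >= |observed delta|\}) / (n_sims + 1), the
#' add-one continuity correction that keeps p > 0. The null sample at the
#' nearest available depth is used when the exact depth was not simulated.
#'
#' @param delta Numeric vector of observed delta values.
#' @param depth Read depth(s) for each observation (recycled if length 1).
#' @param null A `bsa_null` object covering the relevant depths.
#' @return Numeric p-value vector, same length as `delta`.
#' @export
empirical_p <- function(delta, depth, null) {
  if (!inherits(null, "bsa_null")) {
    abort("empirical_p: null must be a bsa_null object")
  }
  depth <- rep_len(depth, length(delta))
  d_use <- nearest_match(depth, null$depths)
  p <- rep(NA_real_, length(delta))
  for (d in unique(d_use)) {
    s <- sort(abs(null$samples[[as.character(d)]]))
    n <- length(s)
    i <- which(d_use == d)
    # count of |null| >= |obs| = n - #{ |null| < |obs| }
    ge <- n - findInterval(abs(delta[i]), s, left.open = TRUE)
    p[i] <- (ge + 1) / (n + 1)
  }
  p
}

#' Attach per-SNP empirical p-values to an index table
#'
#' Looks up each SNP's null sample by its mean read depth across the two
#' bulks (rounded, nearest simulated depth) and adds a two-sided empirical
#' p-value for its delta.
#'
#' @param records Index tibble from [compute_snp_index()].
#' @param null A `bsa_null` object.
#' @return `records` with an added `p` column (`NA` where delta is `NA`).
#' @export
add_empirical_p <- function(records, null) {
  if (!"delta" %in% names(records)) {
    abort("add_empirical_p: run compute_snp_index() first")
  }
  mean_depth <- round((records$depth_high + records$depth_low) / 2)
  ok <- !is.na(records$delta)
  p <- rep(NA_real_, nrow(records))
  p[ok] <- empirical_p(records$delta[ok], mean_depth[ok], null)
  dplyr::mutate(records, p = p)
}
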