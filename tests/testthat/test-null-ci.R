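# closed-form null s.d.: Var(delta) = 2 * (1/(8 B) + E[p(1-p)] / d) with
# p = Binomial(2B, 1/2) / (2B), so E[p(1-p)] = 1/4 - 1/(16 B) ... computed
# exactly below from the binomial moments
null_sd <- function(depth, bulk_size) {
  var_p <- 0.25 / (2 * bulk_size)
  e_pq <- 0.25 - var_p
  sqrt(2 * (var_p + e_pq / depth))
}

test_that("null delta s.d. matches the law of total variance", {
  null <- null_delta_distribution(c(29, 10000), bulk_size = 20,
                                  n_sims = 1e5, seed = 2)
  expect_equal(sd(null$samples[["29"]]), null_sd(29, 20), tolerance = 0.01)
  # depth -> infinity limit: only bulk-composition noise, sqrt(2/160)
  expect_equal(sd(null$samples[["10000"]]), sqrt(2 * 0.125 / 20),
               tolerance = 0.01)
  expect_equal(sqrt(2 * 0.125 / 20), 0.1118, tolerance = 1e-4)
  # symmetric about zero
  expect_lt(abs(mean(null$samples[["29"]])),
            3 * null_sd(29, 20) / sqrt(1e5))
})

test_that("confidence bounds shrink with depth and with bulk size", {
  ci_29 <- ci_table(c(29, 58), bulk_size = 20, n_sims = 5e4, seed = 3)
  up <- function(ci, d, l) ci$upper[ci$depth == d & ci$level == l]
  expect_lt(up(ci_29, 58, 0.95), up(ci_29, 29, 0.95))
  expect_lt(up(ci_29, 58, 0.99), up(ci_29, 29, 0.99))
  ci_b40 <- ci_table(29, bulk_size = 40, n_sims = 5e4, seed = 3)
  expect_lt(up(ci_b40, 29, 0.95), up(ci_29, 29, 0.95))
  # bounds symmetric about zero within Monte-Carlo error
  expect_equal(ci_29$upper, -ci_29$lower, tolerance = 0.02)
})

test_that("one-sided bounds are tighter and the null filter drops replicates", {
  null <- null_delta_distribution(29, n_sims = 2e4, seed = 6)
  two <- ci_table(null, levels = 0.95)
  one <- ci_table(null, levels = 0.95, two_sided = FALSE)
  expect_lt(one$upper, two$upper) # 95th < 97.5th percentile
  filt <- null_delta_distribution(29, n_sims = 2e4, seed = 6,
                                  low_index_filter = 0.3)
  expect_lt(length(filt$samples[["29"]]), 2e4)
  expect_true(all(is.finite(filt$samples[["29"]])))
})

test_that("null samples are seed-reproducible and depth-order invariant", {
  a <- null_delta_distribution(c(10, 29), n_sims = 1000, seed = 7)
  b <- null_delta_distribution(c(29, 10), n_sims = 1000, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$samples[["29"]],
                   null_delta_distribution(29, n_sims = 1000,
                                           seed = 7)$samples[["29"]])
})

test_that("empirical p-values behave at the extremes and mid-scale", {
  null <- null_delta_distribution(29, n_sims = 2e4, seed = 4)
  n <- null$n_sims
  expect_equal(empirical_p(0, 29, null), 1, tolerance = 0.01)
  expect_equal(empirical_p(1.0, 29, null), 1 / (n + 1))
  expect_equal(empirical_p(-1.0, 29, null), 1 / (n + 1))
  # self-consistency with the CI table: delta at the 97.5th percentile of
  # the null has two-sided p ~ 0.05
  # (delta at depth d is supported on multiples of 1/d, so the empirical
  # quantile sits on an atom; allow for the tied mass)
  q975 <- stats::quantile(null$samples[["29"]], 0.975, names = FALSE)
  expect_lt(abs(empirical_p(q975, 29, null) - 0.05), 0.01)
  # nearest-depth fallback
  expect_equal(empirical_p(0.2, 31, null), empirical_p(0.2, 29, null))
})

test_that("per-SNP p-values join on the mean bulk depth", {
  null <- null_delta_distribution(c(20, 30), n_sims = 5000, seed = 5)
  recs <- compute_snp_index(tibble::tibble(
    chrom = "chr1", pos = c(100, 200),
    donor_count_high = c(18, 15), depth_high = c(20, 30),
    donor_count_low = c(2, 15), depth_low = c(20, 30)))
  out <- add_empirical_p(recs, null)
  expect_equal(out$p[1], empirical_p(0.8, 20, null))
  expect_equal(out$p[2], empirical_p(0, 30, null))
  expect_lt(out$p[1], 0.05)
  expect_gt(out$p[2], 0.5)
})
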