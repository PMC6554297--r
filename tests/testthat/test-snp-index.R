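counts_row <- function(dh, nh, dl, nl, pos = 100) {
  tibble::tibble(chrom = "chr1", pos = pos,
                 donor_count_high = nh, depth_high = dh,
                 donor_count_low = nl, depth_low = dl)
}

test_that("SNP index and delta follow the defining arithmetic", {
  r <- compute_snp_index(counts_row(30, 15, 30, 15))
  expect_equal(r$index_high, 0.5)
  expect_equal(r$index_low, 0.5)
  expect_equal(r$delta, 0)

  # bulk-average indices at a strong QTL peak
  r <- compute_snp_index(counts_row(100, 78, 100, 22))
  expect_equal(r$delta, 0.56)

  r <- compute_snp_index(counts_row(29, 22, 29, 7))
  expect_equal(r$delta, 15 / 29)
  expect_equal(r$index_high, 22 / 29)

  expect_error(compute_snp_index(counts_row(10, 11, 10, 5)), "outside")
})

test_that("index bounds hold on random inputs", {
  idx <- compute_snp_index(random_counts(500, seed = 21))
  expect_true(all(idx$index_high >= 0 & idx$index_high <= 1, na.rm = TRUE))
  expect_true(all(idx$index_low >= 0 & idx$index_low <= 1, na.rm = TRUE))
  expect_true(all(idx$delta >= -1 & idx$delta <= 1, na.rm = TRUE))
  expect_equal(idx$delta, idx$index_high - idx$index_low)
})

test_that("depth filter keeps records at the boundary in both bulks", {
  keep <- counts_row(29, 1, 29, 1)
  drop <- counts_row(29, 1, 28, 1)
  both <- dplyr::bind_rows(keep, drop)
  out <- suppressMessages(filter_by_depth(both, min_depth = 29))
  expect_equal(nrow(out), 1)
  expect_equal(out$depth_low, 29)

  # depths 3..12 in both bulks, min_depth 10 -> 3 survivors (10, 11, 12)
  recs <- dplyr::bind_rows(lapply(3:12, function(d) counts_row(d, 1, d, 1)))
  out <- suppressMessages(filter_by_depth(recs, min_depth = 10))
  expect_equal(nrow(out), 3)
  expect_equal(out$depth_high, c(10, 11, 12))

  # alternative combination rules
  mixed <- dplyr::bind_rows(counts_row(29, 1, 28, 1), counts_row(20, 1, 20, 1))
  expect_equal(nrow(suppressMessages(
    filter_by_depth(mixed, 29, rule = "either"))), 1)
  expect_equal(nrow(suppressMessages(
    filter_by_depth(mixed, 40, rule = "sum"))), 2)
  expect_equal(nrow(suppressMessages(
    filter_by_depth(mixed, 58, rule = "sum"))), 0)
})

test_that("low-index filter removes only records low in both bulks, strictly", {
  mk <- function(ih, il) {
    r <- counts_row(100, round(100 * ih), 100, round(100 * il))
    compute_snp_index(r)
  }
  expect_equal(nrow(suppressMessages(filter_low_index_both(mk(0.25, 0.25)))), 0)
  expect_equal(nrow(suppressMessages(filter_low_index_both(mk(0.25, 0.80)))), 1)
  # boundary: exactly 0.30 in one bulk is kept under the strict rule
  expect_equal(nrow(suppressMessages(filter_low_index_both(mk(0.30, 0.29)))), 1)
})

test_that("depth and low-index filters commute", {
  for (s in 1:5) {
    idx <- compute_snp_index(random_counts(200, seed = s))
    a <- suppressMessages(filter_low_index_both(filter_by_depth(idx, 20)))
    b <- suppressMessages(filter_by_depth(filter_low_index_both(idx), 20))
    expect_equal(a, b)
  }
})

test_that("filter record counts match a brute-force re-count", {
  idx <- compute_snp_index(random_counts(300, seed = 8))
  out <- suppressMessages(filter_by_depth(idx, 22))
  expect_equal(nrow(out), sum(idx$depth_high >= 22 & idx$depth_low >= 22))
  out2 <- suppressMessages(filter_low_index_both(idx, 0.3))
  expect_equal(nrow(out2),
               sum(!(idx$index_high < 0.3 & idx$index_low < 0.3)))
})

test_that("null-simulated data centres indices at 0.5 and delta at 0", {
  # linked SNPs are correlated, so the s.e. of the genome-wide mean is
  # taken across chromosomes (independent meioses), not across SNPs
  lens <- rep(5e6, 12)
  names(lens) <- paste0("chr", 1:12)
  map <- build_genome_map(lens, snp_spacing = 1e5)
  sim <- simulate_bsa_experiment(map, qtls = NULL, n_individuals = 178,
                                 bulk_size = 20, seed = 31)
  idx <- suppressMessages(compute_snp_index(sim$counts))
  idx <- idx[!is.na(idx$delta), ]
  cluster_check <- function(v, center) {
    by_chr <- tapply(v, idx$chrom, mean)
    se <- stats::sd(by_chr) / sqrt(length(by_chr))
    expect_lt(abs(mean(by_chr) - center), 3 * se)
  }
  cluster_check(idx$delta, 0)
  cluster_check(idx$index_high, 0.5)
  cluster_check(idx$index_low, 0.5)
})
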