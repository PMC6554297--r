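test_that("bulk allele frequencies are dosage-weighted and sum to one", {
  expect_equal(bulk_allele_frequency(rep(2, 20)), c(donor = 1, other = 0))
  expect_equal(bulk_allele_frequency(c(rep(2, 10), rep(0, 10))),
               c(donor = 0.5, other = 0.5))
  # 12 BB + 6 het + 2 other-homozygous plants: 30/40 donor alleles
  f <- bulk_allele_frequency(c(rep(2, 12), rep(1, 6), rep(0, 2)))
  expect_equal(f, c(donor = 0.75, other = 0.25))
  expect_equal(sum(f), 1)
  expect_error(bulk_allele_frequency(c(NA, NA)), "missing")
  expect_error(bulk_allele_frequency(c(0, 3)), "codes")
})

test_that("a marker unrelated to the trait scores LOD 0, PVE 0", {
  codes <- rep(c(0, 1, 2), each = 4)
  y <- rep(c(1, 2, 3, 4), 3) # identical within-class pattern, slope 0
  fit <- single_marker(codes, y)
  expect_equal(fit$lod, 0, tolerance = 1e-12)
  expect_equal(fit$pve, 0, tolerance = 1e-10)
})

test_that("the additive effect is half the homozygote difference", {
  codes <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  y <- c(-0.105, -0.105, -0.105, 0, 0, 0, 0.105, 0.105, 0.105)
  fit <- suppressWarnings(single_marker(codes, y, donor_parent = "Basmati",
                                        other_parent = "PTT1"))
  expect_equal(fit$additive_effect, 0.105)
  expect_equal(fit$donor, "Basmati")
  expect_equal(fit$pve, 100)
  # donor flips when the phenotype is negated
  expect_equal(suppressWarnings(
    single_marker(codes, -y, donor_parent = "Basmati",
                  other_parent = "PTT1"))$donor, "PTT1")
})

test_that("LOD follows the regression identity, frozen and two-model", {
  # closed form: LOD = -(n/2) log10(1 - R^2); at n = 170, R^2 = 0.1858
  # this is 7.5879 (not sensitive to the data, only to n and R^2)
  expect_equal(bsascan:::lod_from_r2(0.1858, 170), 7.58786, tolerance = 1e-4)

  withr::with_seed(12, {
    codes <- sample(0:2, 170, replace = TRUE, prob = c(.25, .5, .25))
    y <- 0.1 * (codes - 1) + stats::rnorm(170, sd = 0.2)
  })
  fit <- single_marker(codes, y)
  # independent oracle: LOD = (n/2) log10(RSS0 / RSS1)
  rss0 <- sum(stats::resid(stats::lm(y ~ 1))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ codes))^2)
  expect_equal(fit$lod, (170 / 2) * log10(rss0 / rss1), tolerance = 1e-10)
  expect_equal(fit$pve, 100 * (1 - rss1 / rss0), tolerance = 1e-10)
})

test_that("missing genotypes are dropped listwise and degenerates rejected", {
  codes <- c(0, 1, 2, NA, 1)
  y <- c(1, 2, 3, 100, 2.1)
  fit <- single_marker(codes, y)
  expect_equal(fit$n, 4)
  expect_error(single_marker(c(1, 1, 1), 1:3), "constant")
  expect_error(single_marker(c(0, 2), 1:2), ">= 3")
})

test_that("glance/tidy give broom-shaped summaries and marker_scan stacks them", {
  withr::with_seed(3, {
    g <- data.frame(
      m_strong = sample(0:2, 170, TRUE),
      m_null = sample(c("A", "H", "B"), 170, TRUE)
    )
    y <- 0.2 * (g$m_strong - 1) + stats::rnorm(170, sd = 0.15)
  })
  tab <- marker_scan(g, y, donor_parent = "Basmati", other_parent = "PTT1")
  expect_equal(tab$marker, c("m_strong", "m_null"))
  expect_true(tab$significant[1])
  expect_false(tab$significant[2])
  expect_true(all(tab$pve >= 0 & tab$pve <= 100))
  fit <- single_marker(g$m_strong, y)
  expect_equal(names(glance(fit)),
               c("marker", "n", "lod", "pve", "additive_effect", "donor"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
})

test_that("the 2-df genotype model bounds the additive fit from above", {
  withr::with_seed(8, {
    codes <- sample(0:2, 120, TRUE)
    y <- c(-0.3, 0.25, 0.3)[codes + 1] + stats::rnorm(120, sd = 0.3)
  })
  add <- single_marker(codes, y, model = "additive")
  gen <- single_marker(codes, y, model = "genotype")
  expect_gte(gen$pve, add$pve)
  expect_equal(gen$additive_effect,
               abs(mean(y[codes == 2]) - mean(y[codes == 0])) / 2)
})

test_that("joint PVE is monotone and decomposes for orthogonal markers", {
  withr::with_seed(4, {
    g1 <- rep(0:2, length.out = 90)
    g2 <- rep(rep(0:2, each = 30), length.out = 90) # orthogonal by design
    y_noiseless <- 0.5 * (g1 - 1) + 0.25 * (g2 - 1)
  })
  g <- data.frame(g1 = g1, g2 = g2)
  p1 <- single_marker(g1, y_noiseless)$pve
  p2 <- single_marker(g2, y_noiseless)$pve
  pj <- suppressWarnings(joint_pve(g, y_noiseless))
  expect_equal(as.numeric(pj), p1 + p2, tolerance = 1e-8)
  expect_gte(pj + 1e-8, max(p1, p2))
  # identical markers: collinear column dropped, joint PVE = single PVE
  y <- y_noiseless + withr::with_seed(5, stats::rnorm(90, sd = 0.3))
  pj2 <- suppressMessages(joint_pve(data.frame(a = g1, b = g1), y))
  expect_equal(as.numeric(pj2), single_marker(g1, y)$pve, tolerance = 1e-10)
  expect_equal(attr(pj2, "dropped"), "b")
  expect_error(joint_pve(data.frame(a = g1), y), ">= 2 markers")
})

test_that("joint PVE recovers the simulated heritability for two QTLs", {
  map <- build_genome_map(c(chr1 = 2e6, chr2 = 2e6), snps_per_chrom = 2)
  pves <- vapply(1:100, function(s) {
    dos <- simulate_f2(map, 170, seed = s)
    qtls <- data.frame(chrom = c("chr1", "chr2"), pos = c(1, 1),
                       additive_effect = 0.5)
    y <- simulate_phenotypes(dos, qtls, heritability = 0.4, seed = s)
    g <- data.frame(q1 = dos[, "chr1:1"], q2 = dos[, "chr2:1"])
    as.numeric(joint_pve(g, y))
  }, numeric(1))
  expect_lt(abs(mean(pves) - 40), 5)
})

test_that("GE ratio is the mean cooked/milled length ratio over replicates", {
  mk <- function(cooked, milled) {
    data.frame(replicate = rep(1:3, each = 2),
               state = rep(c("cooked", "milled"), 3),
               length_mm = rep(c(cooked, milled), 3))
  }
  high <- ge_ratio(mk(14.47, 6.38))
  expect_equal(high$ge_ratio, 14.47 / 6.38, tolerance = 1e-12)
  expect_equal(round(high$ge_ratio, 2), 2.27)
  low <- ge_ratio(mk(11.09, 7.36))
  expect_equal(round(low$ge_ratio, 2), 1.51)
  same <- ge_ratio(mk(7.0, 7.0))
  expect_equal(same$ge_ratio, 1)
  expect_equal(same$sd, 0)
  # scale invariance
  d <- mk(14.47, 6.38)
  d2 <- d
  d2$length_mm <- d2$length_mm * 3.7
  expect_equal(ge_ratio(d2)$ge_ratio, high$ge_ratio)
  bad <- d
  bad$length_mm[1] <- -1
  expect_error(ge_ratio(bad), "positive")
  expect_error(ge_ratio(d[d$state == "cooked", ]), "both cooked and milled")
})
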