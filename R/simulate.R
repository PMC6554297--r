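#' Simulate F2 genotypes by Haldane meiosis
#'
#' Draws an F2 population from a cross of two fully inbred parents. Each
#' individual is the sum of two independent gametes; each gamete is
#' generated per chromosome with a Poisson number of crossovers (mean equal
#' to the genetic length in Morgans, from the map's cM/Mb rate) placed
#' uniformly, and a fair coin for the phase at the left telomere. This is
#' the Haldane model: no crossover interference, so the recombination
#' fraction between two loci at genetic distance m Morgans is
#' r = (1 - exp(-2m)) / 2.
#'
#' @param map A [build_genome_map()] object.
#' @param n Number of F2 individuals (>= 2).
#' @param seed Integer seed; identical seeds give identical populations.
#' @return Integer matrix `n` x n_SNPs of donor-allele dosages in {0, 1, 2};
#'   columns named `chrom:pos` in map order.
#' @export
simulate_f2 <- function(map, n, seed = 1) {
  if (n < 2) abort("simulate_f2: n must be >= 2")
  cm <- map_cm_per_mb(map)
  lens <- map_chrom_lengths(map)
  withr::with_seed(derive_seed(seed, "meiosis"), {
    per_chrom <- purrr::imap(lens, function(len, nm) {
      g <- genetic_pos(map$pos[map$chrom == nm], cm)
      L <- genetic_pos(len, cm)
      sim_gametes(g, L, 2L * n)
    })
  })
  dos <- purrr::imap(per_chrom, function(al, nm) {
    d <- al[seq_len(nrow(al) / 2) * 2L - 1L, , drop = FALSE] +
      al[seq_len(nrow(al) / 2) * 2L, , drop = FALSE]
    colnames(d) <- snp_id(nm, map$pos[map$chrom == nm])
    d
  })
  do.call(cbind, unname(dos))
}

# gamete alleles (0 = recurrent, 1 = donor) at genetic positions g on a
# chromosome of genetic length L, for n_gam gametes
sim_gametes <- function(g, L, n_gam) {
  k <- stats::rpois(n_gam, L)
  phase <- sample(0:1, n_gam, replace = TRUE)
  al <- matrix(0L, n_gam, length(g))
  for (i in seq_len(n_gam)) {
    if (k[i] == 0L) {
      al[i, ] <- phase[i]
    } else {
      xo <- sort(stats::runif(k[i], 0, L))
      al[i, ] <- (phase[i] + findInterval(g, xo)) %% 2L
    }
  }
  al
}

#' Simulate quantitative phenotypes over a set of QTLs
#'
#' Genetic value per individual is the sum over QTLs of (-a, d, +a) for
#' donor dosage (0, 1, 2); Gaussian residual noise is scaled so that the
#' realized genetic variance is the requested fraction of the total
#' (narrow-plus-dominance heritability). `heritability = 0` returns pure
#' unit-variance noise.
#'
#' @param dosages Dosage matrix from [simulate_f2()].
#' @param qtls Data frame with columns `chrom`, `pos`, `additive_effect`
#'   and optionally `dominance` (default 0). Every QTL must sit on a mapped
#'   SNP (a column of `dosages`).
#' @param heritability Fraction of phenotypic variance that is genetic,
#'   in `[0, 1)`.
#' @param seed Integer seed for the residual noise.
#' @return Numeric phenotype vector, one value per row of `dosages`.
#' @export
simulate_phenotypes <- function(dosages, qtls, heritability, seed = 1) {
  if (heritability < 0 || heritability >= 1) {
    abort("simulate_phenotypes: heritability must be in [0, 1)")
  }
  n <- nrow(dosages)
  if (!"dominance" %in% names(qtls)) qtls$dominance <- 0
  ids <- snp_id(qtls$chrom, qtls$pos)
  off <- setdiff(ids, colnames(dosages))
  if (length(off) > 0) {
    abort(paste0("simulate_phenotypes: QTL not on the map: ",
                 paste(off, collapse = ", ")))
  }
  genetic <- rep(0, n)
  for (i in seq_along(ids)) {
    d <- dosages[, ids[i]]
    a <- qtls$additive_effect[i]
    genetic <- genetic + c(-a, qtls$dominance[i], a)[d + 1L]
  }
  withr::with_seed(derive_seed(seed, "phenotype"), {
    if (heritability == 0) {
      return(stats::rnorm(n))
    }
    var_g <- stats::var(genetic)
    if (var_g == 0) {
      warn("simulate_phenotypes: no genetic variance; returning pure noise")
      return(stats::rnorm(n))
    }
    var_e <- var_g * (1 - heritability) / heritability
    genetic + stats::rnorm(n, sd = sqrt(var_e))
  })
}

#' Select extreme-phenotype bulks
#'
#' Picks the `bulk_size` individuals with the largest phenotypes (high bulk)
#' and the `bulk_size` with the smallest (low bulk), the sampling design of
#' bulked-segregant analysis. Ties break deterministically by ascending
#' individual index, so the bulks are always disjoint.
#'
#' @param phenotypes Numeric vector.
#' @param bulk_size Number of individuals per bulk; `2 * bulk_size` must not
#'   exceed the population size.
#' @return List with integer index vectors `low` and `high` (ascending).
#' @export
select_bulks <- function(phenotypes, bulk_size = 20) {
  n <- length(phenotypes)
  if (bulk_size < 1) abort("select_bulks: bulk_size must be >= 1")
  if (2 * bulk_size > n) {
    abort("select_bulks: 2 * bulk_size exceeds the population size")
  }
  ord <- order(phenotypes, seq_len(n))
  list(low = sort(ord[seq_len(bulk_size)]),
       high = sort(ord[seq(n - bulk_size + 1L, n)]))
}

#' Simulate pooled short-read allele counts for two bulks
#'
#' Emulates equal-contribution DNA pooling and shotgun sequencing of the
#' two bulks: at each SNP the bulk's donor-allele frequency is the mean
#' dosage over its members divided by 2; per-SNP read depth is drawn from
#' the depth model independently per bulk; a symmetric per-read error `e`
#' perturbs the sampled frequency to `p(1-e) + (1-p)e`; and the donor read
#' count is Binomial(depth, p'). Zero-depth draws are retained (their SNP
#' index is undefined and such records are excluded downstream).
#'
#' @param dosages Dosage matrix from [simulate_f2()].
#' @param bulks List with `high` and `low` index vectors, as returned by
#'   [select_bulks()].
#' @param depth_mean Mean read depth per bulk (default 22, typical of a
#'   ~20x bulk resequencing design).
#' @param depth_model `"poisson"` (depth ~ Poisson(depth_mean)) or
#'   `"fixed"`.
#' @param sequencing_error Per-read allele flip probability in `[0, 0.01]`.
#' @param seed Integer seed.
#' @return Tibble of per-SNP count records: `chrom`, `pos`,
#'   `donor_count_high`, `depth_high`, `donor_count_low`, `depth_low`.
#' @export
simulate_bulk_reads <- function(dosages, bulks, depth_mean = 22,
                                depth_model = c("poisson", "fixed"),
                                sequencing_error = 0.001, seed = 1) {
  depth_model <- match.arg(depth_model)
  if (depth_mean < 1) abort("simulate_bulk_reads: mean depth must be >= 1")
  if (sequencing_error < 0 || sequencing_error > 0.01) {
    abort("simulate_bulk_reads: sequencing_error must be in [0, 0.01]")
  }
  if (length(bulks$high) < 1 || length(bulks$low) < 1) {
    abort("simulate_bulk_reads: bulks must be non-empty")
  }
  ids <- colnames(dosages)
  m <- length(ids)
  e <- sequencing_error

  sample_bulk <- function(idx) {
    p <- colMeans(dosages[idx, , drop = FALSE]) / 2
    p_eff <- p * (1 - e) + (1 - p) * e
    depth <- switch(depth_model,
                    poisson = stats::rpois(m, depth_mean),
                    fixed   = rep(as.integer(round(depth_mean)), m))
    list(count = stats::rbinom(m, depth, p_eff), depth = depth)
  }

  withr::with_seed(derive_seed(seed, "reads"), {
    hi <- sample_bulk(bulks$high)
    lo <- sample_bulk(bulks$low)
  })
  chrom <- sub(":[0-9]+$", "", ids)
  pos <- as.numeric(sub("^.*:", "", ids))
  tibble(chrom = chrom, pos = pos,
         donor_count_high = hi$count, depth_high = hi$depth,
         donor_count_low = lo$count, depth_low = lo$depth)
}

#' Simulate a complete F2 bulked-segregant experiment
#'
#' Convenience wrapper chaining [simulate_f2()], [simulate_phenotypes()],
#' [select_bulks()] and [simulate_bulk_reads()] from one root seed (each
#' stage uses an independent derived substream).
#'
#' @inheritParams simulate_f2
#' @inheritParams simulate_phenotypes
#' @inheritParams simulate_bulk_reads
#' @param n_individuals F2 population size (default 178).
#' @param bulk_size Plants per bulk (default 20).
#' @return List of class `bsa_sim`: `counts` (per-SNP record tibble),
#'   `genotypes`, `phenotypes`, `bulks`, and the call parameters.
#' @examples
#' map <- build_genome_map(c(chr6 = 31e6), snp_spacing = 500e3)
#' sim <- simulate_bsa_experiment(map,
#'   qtls = data.frame(chrom = "chr6", pos = 6.5e6, additive_effect = 1),
#'   heritability = 0.8, seed = 7)
#' head(sim$counts)
#' @export
simulate_bsa_experiment <- function(map, qtls = NULL, n_individuals = 178,
                                    heritability = 0.5, bulk_size = 20,
                                    depth_mean = 22,
                                    depth_model = c("poisson", "fixed"),
                                    sequencing_error = 0.001, seed = 1) {
  depth_model <- match.arg(depth_model)
  if (2 * bulk_size > n_individuals) {
    abort("simulate_bsa_experiment: 2 * bulk_size exceeds n_individuals")
  }
  dos <- simulate_f2(map, n_individuals, seed = seed)
  if (is.null(qtls) || nrow(qtls) == 0) {
    phe <- withr::with_seed(derive_seed(seed, "phenotype"),
                            stats::rnorm(n_individuals))
  } else {
    phe <- simulate_phenotypes(dos, qtls, heritability, seed = seed)
  }
  bulks <- select_bulks(phe, bulk_size)
  counts <- simulate_bulk_reads(dos, bulks, depth_mean = depth_mean,
                                depth_model = depth_model,
                                sequencing_error = sequencing_error,
                                seed = seed)
  structure(list(counts = counts, genotypes = dos, phenotypes = phe,
                 bulks = bulks,
                 params = list(n_individuals = n_individuals,
                               heritability = heritability,
                               bulk_size = bulk_size,
                               depth_mean = depth_mean,
                               depth_model = depth_model,
                               sequencing_error = sequencing_error,
                               seed = seed)),
            class = "bsa_sim")
}

#' @export
print.bsa_sim <- function(x, ...) {
  p <- x$params
  cat("F2 bulked-segregant simulation\n")
  cat("  individuals:", p$n_individuals, " bulk size:", p$bulk_size, "\n")
  cat("  SNPs:", nrow(x$counts), " depth:", p$depth_model,
      paste0("(mean ", p$depth_mean, ")"), " h2:", p$heritability, "\n")
  cat("  seed:", p$seed, "\n")
  invisible(x)
}
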