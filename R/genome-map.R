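#' Build a marker map for a simulated genome
#'
#' Lays out SNP positions on a set of chromosomes, either on a regular grid
#' (`snp_spacing`) or as a fixed number of evenly spaced SNPs per chromosome
#' (`snps_per_chrom`). The map carries a single genome-wide recombination
#' rate in centimorgan per megabase, used by [simulate_f2()] to convert
#' physical to genetic distance.
#'
#' @param chrom_lengths Numeric vector of chromosome lengths in bp. Names
#'   are used as chromosome names; unnamed vectors get `chr1`, `chr2`, ...
#' @param snp_spacing Distance in bp between consecutive SNPs. The first SNP
#'   sits at `snp_spacing`, so a 1 Mb chromosome at 250 kb spacing carries
#'   SNPs at 250, 500, 750 and 1000 kb.
#' @param snps_per_chrom Alternative to `snp_spacing`: the number of evenly
#'   spaced SNPs placed on every chromosome.
#' @param cm_per_mb Recombination rate, centimorgan per megabase. The
#'   default 4 cM/Mb is rice-scale (~1500 cM over a ~373 Mb genome).
#'
#' @return A tibble of class `genome_map` with columns `chrom` and `pos`
#'   (1-based bp, strictly increasing within chromosome), and attributes
#'   `chrom_lengths` and `cm_per_mb`.
#' @examples
#' build_genome_map(c(chr1 = 1e6), snp_spacing = 250e3)
#' @export
build_genome_map <- function(chrom_lengths, snp_spacing = NULL,
                             snps_per_chrom = NULL, cm_per_mb = 4) {
  if (length(chrom_lengths) < 1 || any(!is.finite(chrom_lengths)) ||
      any(chrom_lengths <= 0)) {
    abort("build_genome_map: chromosome lengths must be positive and finite")
  }
  if (!is.numeric(cm_per_mb) || cm_per_mb <= 0) {
    abort("build_genome_map: cm_per_mb must be > 0")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (is.null(snp_spacing) == is.null(snps_per_chrom)) {
    abort("build_genome_map: supply exactly one of snp_spacing, snps_per_chrom")
  }

  pos_for <- function(len) {
    if (!is.null(snp_spacing)) {
      if (snp_spacing <= 0) {
        abort("build_genome_map: snp_spacing must be > 0")
      }
      p <- seq(snp_spacing, len, by = snp_spacing)
    } else {
      if (snps_per_chrom < 2) {
        abort("build_genome_map: snps_per_chrom must be >= 2")
      }
      p <- round(seq(1, len, length.out = snps_per_chrom))
    }
    p <- unique(as.numeric(p))
    if (length(p) < 2) {
      abort("build_genome_map: spacing must yield >= 2 SNPs per chromosome")
    }
    p
  }

  map <- purrr::imap(chrom_lengths,
                     \(len, nm) tibble(chrom = nm, pos = pos_for(len))) |>
    purrr::list_rbind()
  structure(map,
            chrom_lengths = chrom_lengths,
            cm_per_mb = cm_per_mb,
            class = c("genome_map", class(tibble())))
}

map_chrom_lengths <- function(map) attr(map, "chrom_lengths")
map_cm_per_mb <- function(map) attr(map, "cm_per_mb")

# genetic positions in Morgans
genetic_pos <- function(pos_bp, cm_per_mb) pos_bp / 1e6 * cm_per_mb / 100
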