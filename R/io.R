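header_lines <- function(params = NULL, seed = NULL) {
  h <- paste0("# bsascan ", as.character(utils::packageVersion("bsascan")))
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  if (!is.null(params) && length(params) > 0) {
    h <- c(h, paste0("# params: ",
                     paste(names(params), unlist(params), sep = "=",
                           collapse = " ")))
  }
  h
}

write_tsv_with_header <- function(x, path, params = NULL, seed = NULL) {
  readr::write_lines(header_lines(params, seed), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a per-SNP bulk count table from TSV
#'
#' Expects a header row with the six columns `chrom`, `pos`,
#' `donor_count_high`, `depth_high`, `donor_count_low`, `depth_low`
#' (comment lines starting with `#` are ignored). Rows where a donor count
#' falls outside `[0, depth]` are rejected with their row numbers.
#'
#' @param path File path.
#' @return Count tibble suitable for [compute_snp_index()].
#' @export
read_counts_tsv <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  assert_count_columns(x, "read_counts_tsv")
  x <- dplyr::mutate(x, dplyr::across(-"chrom", as.numeric))
  bad <- which(x$donor_count_high < 0 | x$donor_count_high > x$depth_high |
                 x$donor_count_low < 0 | x$donor_count_low > x$depth_low)
  if (length(bad) > 0) {
    abort(paste0("read_counts_tsv: donor count outside [0, depth] at data row(s) ",
                 paste(bad, collapse = ", ")))
  }
  x
}

#' Write a per-SNP bulk count table as TSV
#'
#' @param counts Count tibble.
#' @param path Output path.
#' @param params,seed Optional run metadata recorded as `#` header comments.
#' @export
write_counts_tsv <- function(counts, path, params = NULL, seed = NULL) {
  assert_count_columns(counts, "write_counts_tsv")
  cols <- c("chrom", "pos", "donor_count_high", "depth_high",
            "donor_count_low", "depth_low")
  write_tsv_with_header(counts[cols], path, params, seed)
}

#' Read bulk allele counts from an allele-depth VCF
#'
#' Parses a VCF 4.x with two named bulk samples carrying `AD` (ref,alt
#' allele depth) FORMAT fields. Only biallelic SNPs are kept; multiallelic
#' sites and indels are skipped with a reported count. The donor allele is
#' taken to be ALT, i.e. counts are polarized to the non-reference parent
#' (the caller's contract).
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param high_sample,low_sample Sample names of the high- and low-
#'   phenotype bulks (default `"HGE"` / `"LGE"`).
#' @return Count tibble suitable for [compute_snp_index()].
#' @export
read_counts_vcf <- function(path, high_sample = "HGE", low_sample = "LGE") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(high_sample, low_sample)) {
    if (!s %in% samples) {
      abort(paste0("read_counts_vcf: sample '", s, "' not in VCF (has: ",
                   paste(samples, collapse = ", "), ")"))
    }
  }
  fix <- vcf@fix
  biallelic_snp <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skip <- sum(!biallelic_snp)
  if (n_skip > 0) {
    inform(paste0("read_counts_vcf: skipped ", n_skip,
                  " multiallelic/indel record(s)"))
  }
  if (!any(grepl("AD", vcf@gt[, 1]))) {
    abort(paste0("read_counts_vcf: no AD field in FORMAT for samples ",
                 high_sample, "/", low_sample))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  parse_ad <- function(s, sample) {
    if (anyNA(s)) {
      abort(paste0("read_counts_vcf: missing AD value(s) for sample ", sample))
    }
    parts <- stringr::str_split_fixed(s, ",", 2)
    list(ref = as.numeric(parts[, 1]), alt = as.numeric(parts[, 2]))
  }
  hi <- parse_ad(ad[biallelic_snp, high_sample], high_sample)
  lo <- parse_ad(ad[biallelic_snp, low_sample], low_sample)
  tibble(chrom = fix[biallelic_snp, "CHROM"],
         pos = as.numeric(fix[biallelic_snp, "POS"]),
         donor_count_high = hi$alt, depth_high = hi$ref + hi$alt,
         donor_count_low = lo$alt, depth_low = lo$ref + lo$alt)
}

#' Write bulk allele counts as a minimal allele-depth VCF 4.2
#'
#' Two samples (high bulk first), genotypes left uncalled (`./.`), `AD`
#' holding ref,donor read counts. Placeholder REF/ALT bases are written
#' (the simulator tracks alleles as ref-parent vs donor, not nucleotides);
#' positions are 1-based per VCF convention.
#'
#' @inheritParams write_counts_tsv
#' @param high_sample,low_sample Sample names (default `"HGE"` / `"LGE"`).
#' @export
write_counts_vcf <- function(counts, path, high_sample = "HGE",
                             low_sample = "LGE", seed = NULL) {
  assert_count_columns(counts, "write_counts_vcf")
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=bsascan_", utils::packageVersion("bsascan"),
           if (!is.null(seed)) paste0(";seed=", seed) else ""),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,donor)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", high_sample, low_sample, sep = "\t")
  )
  body <- paste(
    counts$chrom, format(counts$pos, scientific = FALSE, trim = TRUE),
    ".", "A", "T", ".", "PASS", ".", "GT:AD",
    paste0("./.:", counts$depth_high - counts$donor_count_high, ",",
           counts$donor_count_high),
    paste0("./.:", counts$depth_low - counts$donor_count_low, ",",
           counts$donor_count_low),
    sep = "\t")
  readr::write_lines(c(meta, body), path)
  invisible(path)
}

#' Write called regions as BED
#'
#' BED is 0-based half-open, so a region `[start, end]` (1-based inclusive)
#' is written as `start-1`, `end`.
#'
#' @param regions A [qtl_regions()] tibble.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- if (nrow(regions) == 0) character(0) else {
    paste(regions$chrom,
          format(regions$start - 1, scientific = FALSE, trim = TRUE),
          format(regions$end, scientific = FALSE, trim = TRUE),
          paste0("region_", seq_len(nrow(regions))),
          sep = "\t")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Run the scan pipeline end to end from a configuration
#'
#' Reads (or simulates) per-SNP counts, runs [run_bsa_scan()], and writes
#' the per-SNP index TSV, window TSV, CI table TSV, region TSV and region
#' BED, each stamped with a header recording the package version, seed and
#' stage parameters. Identical configuration and seed give byte-identical
#' outputs.
#'
#' @param config A named list, or path to a YAML/JSON file holding one.
#'   Recognized fields: `counts_tsv` or `counts_vcf` (input; alternatively
#'   `simulate`, a list of [simulate_bsa_experiment()] arguments plus
#'   `chrom_lengths` and `snp_spacing`), `out_prefix` (required), `seed`,
#'   and any of the [run_bsa_scan()] parameters (`min_depth`,
#'   `low_index_threshold`, `window_bp`, `step_bp`, `min_snps`, `level`,
#'   `p_threshold`, `max_gap_windows`, `bulk_size`, `n_sims`,
#'   `donor_high`, `donor_low`).
#' @return Invisibly, a list with the `bsa_scan` result and the `paths` of
#'   all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_prefix)) {
    abort("run_pipeline: config must set out_prefix")
  }
  scan_args <- config[intersect(names(config),
                                c("min_depth", "low_index_threshold",
                                  "window_bp", "step_bp", "min_snps",
                                  "level", "p_threshold", "max_gap_windows",
                                  "bulk_size", "n_sims", "donor_high",
                                  "donor_low"))]
  seed <- config$seed %||% 1L
  if (!is.null(config$window_bp) && !is.null(config$step_bp) &&
      config$step_bp > config$window_bp) {
    abort("run_pipeline: step_bp must not exceed window_bp")
  }

  chrom_lengths <- NULL
  if (!is.null(config$counts_tsv)) {
    inform(paste0("run_pipeline: reading counts from ", config$counts_tsv))
    counts <- read_counts_tsv(config$counts_tsv)
  } else if (!is.null(config$counts_vcf)) {
    inform(paste0("run_pipeline: reading counts from ", config$counts_vcf))
    counts <- read_counts_vcf(config$counts_vcf)
  } else if (!is.null(config$simulate)) {
    sc <- config$simulate
    lens <- unlist(sc$chrom_lengths)
    map <- build_genome_map(lens, snp_spacing = sc$snp_spacing %||% 5e4,
                            cm_per_mb = sc$cm_per_mb %||% 4)
    chrom_lengths <- map_chrom_lengths(map)
    qtls <- if (!is.null(sc$qtls)) {
      dplyr::bind_rows(lapply(sc$qtls, as.data.frame))
    }
    sim <- simulate_bsa_experiment(
      map, qtls = qtls,
      n_individuals = sc$n_individuals %||% 178,
      heritability = sc$heritability %||% 0.5,
      bulk_size = sc$bulk_size %||% 20,
      depth_mean = sc$depth_mean %||% 22,
      depth_model = sc$depth_model %||% "poisson",
      sequencing_error = sc$sequencing_error %||% 0.001,
      seed = seed)
    counts <- sim$counts
    inform(paste0("run_pipeline: simulated ", nrow(counts), " SNPs"))
  } else {
    abort("run_pipeline: config must set counts_tsv, counts_vcf or simulate")
  }

  scan <- do.call(run_bsa_scan,
                  c(list(counts = counts, seed = seed,
                         chrom_lengths = chrom_lengths), scan_args))

  pfx <- config$out_prefix
  dir.create(dirname(pfx), recursive = TRUE, showWarnings = FALSE)
  p <- scan$params
  paths <- list(
    counts = paste0(pfx, "_counts.tsv"),
    index = paste0(pfx, "_index.tsv"),
    windows = paste0(pfx, "_windows.tsv"),
    ci = paste0(pfx, "_ci.tsv"),
    regions = paste0(pfx, "_regions.tsv"),
    bed = paste0(pfx, "_regions.bed")
  )
  write_counts_tsv(counts, paths$counts, seed = seed)
  write_tsv_with_header(scan$snps, paths$index, p, seed)
  write_tsv_with_header(scan$windows, paths$windows, p, seed)
  write_tsv_with_header(as_tibble(scan$ci), paths$ci, p, seed)
  write_tsv_with_header(scan$regions, paths$regions, p, seed)
  write_regions_bed(scan$regions, paths$bed)
  inform(paste0("run_pipeline: wrote ", length(paths), " artifact(s) to ",
                pfx, "_*"))
  invisible(list(scan = scan, paths = paths))
}
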