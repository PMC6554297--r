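#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# One root seed per experiment; each stochastic stage draws from its own
# substream so stages can be re-run independently and still reproduce.
# Derived seeds stay below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage, extra = 0L) {
  offsets <- c(meiosis = 11L, phenotype = 23L, reads = 37L, null = 53L,
               pipeline = 71L)
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown RNG stage '", stage, "'"))
  }
  s <- (as.numeric(seed) * 7919 + offsets[[stage]] * 104729 +
          as.numeric(extra) * 131) %% 2147483399
  as.integer(s) + 1L
}

snp_id <- function(chrom, pos) {
  paste0(chrom, ":", format(pos, scientific = FALSE, trim = TRUE))
}

assert_count_columns <- function(x, call_fn) {
  need <- c("chrom", "pos", "donor_count_high", "depth_high",
            "donor_count_low", "depth_low")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0(call_fn, ": missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(x)
}

assert_sorted_records <- function(x, call_fn) {
  bad <- x |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(unsorted = is.unsorted(.data$pos), .groups = "drop")
  if (any(bad$unsorted)) {
    abort(paste0(call_fn, ": records must be sorted by position within ",
                 "chromosome (offending: ",
                 paste(bad$chrom[bad$unsorted], collapse = ", "), ")"))
  }
  invisible(x)
}

#' @export
generics::tidy

#' @export
generics::glance
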