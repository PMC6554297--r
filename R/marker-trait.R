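#' Donor-allele frequency within a bulk
#'
#' Frequency of the donor allele among the genotyped individuals of a bulk:
#' (sum of dosages) / (2 x number of non-missing genotypes). The pair of
#' frequencies sums to one.
#'
#' @param codes Donor-allele dosages in {0, 1, 2}; `NA` allowed.
#' @return Named numeric vector `c(donor = ..., other = ...)`.
#' @examples
#' bulk_allele_frequency(c(rep(2, 12), rep(1, 6), rep(0, 2)))
#' @export
bulk_allele_frequency <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) {
    abort("bulk_allele_frequency: all genotypes missing")
  }
  if (!all(codes %in% 0:2)) {
    abort("bulk_allele_frequency: codes must be 0, 1 or 2")
  }
  donor <- sum(codes) / (2 * length(codes))
  c(donor = donor, other = 1 - donor)
}

#' Recode A/H/B marker calls to donor-allele dosage
#'
#' `A` = homozygous recurrent parent (0), `H` = heterozygous (1), `B` =
#' homozygous donor parent (2). Numeric 0/1/2 input passes through;
#' anything else becomes `NA`.
#'
#' @param x Character or numeric vector of genotype calls.
#' @return Integer dosage vector with `NA` for missing/unknown calls.
#' @export
recode_genotypes <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
    out[!out %in% 0:2] <- NA_integer_
    return(out)
  }
  unname(c(A = 0L, H = 1L, B = 2L)[toupper(as.character(x))])
}

lod_from_r2 <- function(r2, n) -(n / 2) * log10(1 - r2)

#' Single-marker association with a quantitative trait
#'
#' Ordinary least-squares regression of phenotype on donor-allele dosage
#' coded (-1, 0, +1) for (0, 1, 2) ("additive" model), or a 2-df
#' genotype-class model ("genotype"). Reports the LOD score
#' `-(n/2) log10(1 - R^2)`, the percent variance explained `100 R^2`, the
#' additive effect (the slope, i.e. half the homozygote difference under
#' pure additivity), and the donor parent (the parent whose allele has a
#' positive slope). Missing genotypes or phenotypes are dropped listwise.
#'
#' @param codes Donor-allele dosages in {0, 1, 2} (`NA` allowed).
#' @param phenotypes Trait values, same length.
#' @param marker Marker name carried into the result.
#' @param model `"additive"` (default) or `"genotype"` for the 2-df
#'   genotype-class fit (the additive effect is then half the difference of
#'   homozygote class means).
#' @param donor_parent,other_parent Parent labels; `donor_parent` donates
#'   the dosage-2 allele.
#' @return Object of class `marker_fit` with [tidy()] and [glance()]
#'   methods; `glance()` gives the marker-table row (marker, n, lod, pve,
#'   additive_effect, donor).
#' @examples
#' fit <- single_marker(c(0, 0, 1, 1, 2, 2), c(1, 1.1, 2, 2.2, 3, 3.1))
#' glance(fit)
#' @export
single_marker <- function(codes, phenotypes, marker = "marker",
                          model = c("additive", "genotype"),
                          donor_parent = "donor", other_parent = "other") {
  model <- match.arg(model)
  ok <- !is.na(codes) & !is.na(phenotypes)
  codes <- codes[ok]
  y <- phenotypes[ok]
  n <- length(y)
  if (n < 3) abort("single_marker: need >= 3 non-missing pairs")
  if (stats::var(codes) == 0) {
    abort(paste0("single_marker: genotype is constant for ", marker))
  }
  x <- codes - 1
  fit <- if (model == "additive") {
    stats::lm(y ~ x)
  } else {
    stats::lm(y ~ factor(codes))
  }
  r2 <- summary(fit)$r.squared
  slope <- if (model == "additive") {
    unname(stats::coef(fit)[2])
  } else {
    # half the homozygote difference; falls back to the additive slope if a
    # homozygote class is absent
    if (all(c(0, 2) %in% codes)) {
      (mean(y[codes == 2]) - mean(y[codes == 0])) / 2
    } else {
      unname(stats::coef(stats::lm(y ~ x))[2])
    }
  }
  structure(list(marker = marker, n = n, r_squared = r2,
                 lod = lod_from_r2(r2, n), pve = 100 * r2,
                 additive_effect = abs(slope),
                 donor = if (slope >= 0) donor_parent else other_parent,
                 model = model, fit = fit),
            class = "marker_fit")
}

#' @export
print.marker_fit <- function(x, ...) {
  cat("Single-marker fit:", x$marker, paste0("(", x$model, " model, n = ",
                                             x$n, ")"), "\n")
  cat(sprintf("  LOD %.2f  PVE %.2f%%  additive effect %.4g  donor %s\n",
              x$lod, x$pve, x$additive_effect, x$donor))
  invisible(x)
}

#' @rdname single_marker
#' @param x A `marker_fit` object.
#' @param ... Unused.
#' @export
tidy.marker_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname single_marker
#' @export
glance.marker_fit <- function(x, ...) {
  tibble(marker = x$marker, n = x$n, lod = x$lod, pve = x$pve,
         additive_effect = x$additive_effect, donor = x$donor)
}

#' Scan a marker genotype table against a phenotype
#'
#' Runs [single_marker()] on every marker column and stacks the
#' `glance()` rows into a marker summary table, flagging markers whose LOD
#' clears the reporting threshold.
#'
#' @param genotypes Data frame, one column per marker, rows = individuals;
#'   codes 0/1/2 or A/H/B (see [recode_genotypes()]).
#' @param phenotypes Trait vector, one value per row of `genotypes`.
#' @param lod_threshold LOD above which a marker is flagged significant
#'   (default 3, the conventional single-marker reporting cutoff).
#' @inheritParams single_marker
#' @return Tibble with one row per marker: `marker`, `n`, `lod`, `pve`,
#'   `additive_effect`, `donor`, `significant`.
#' @export
marker_scan <- function(genotypes, phenotypes, lod_threshold = 3,
                        model = c("additive", "genotype"),
                        donor_parent = "donor", other_parent = "other") {
  model <- match.arg(model)
  purrr::imap(as.list(genotypes), function(col, nm) {
    glance(single_marker(recode_genotypes(col), phenotypes, marker = nm,
                         model = model, donor_parent = donor_parent,
                         other_parent = other_parent))
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(significant = .data$lod >= lod_threshold)
}

#' Joint phenotypic variance explained by several markers
#'
#' Percent phenotypic variance explained (100 R^2) by the multiple
#' regression of the phenotype on all marker dosages jointly, with listwise
#' deletion of missing values. Columns made redundant by collinearity are
#' dropped by the least-squares fit and reported in a message and the
#' `dropped` attribute.
#'
#' @inheritParams marker_scan
#' @return Percent of variance explained (scalar), with attribute
#'   `dropped` naming any aliased marker columns.
#' @export
joint_pve <- function(genotypes, phenotypes) {
  if (ncol(genotypes) < 2) abort("joint_pve: need >= 2 markers")
  X <- as.data.frame(lapply(genotypes, recode_genotypes))
  keep <- stats::complete.cases(X) & !is.na(phenotypes)
  X <- X[keep, , drop = FALSE]
  y <- phenotypes[keep]
  if (length(y) <= ncol(X) + 1) {
    abort("joint_pve: need n > number of markers + 1 after deletion")
  }
  fit <- stats::lm(y ~ ., data = X)
  dropped <- names(which(is.na(stats::coef(fit))))
  if (length(dropped) > 0) {
    inform(paste0("joint_pve: dropped collinear marker(s): ",
                  paste(dropped, collapse = ", ")))
  }
  structure(100 * summary(fit)$r.squared, dropped = dropped)
}

#' Grain-elongation ratio from replicated length measurements
#'
#' The GE ratio of a line is, per replicate, the mean cooked-grain length
#' divided by the mean milled (raw) grain length; the line value is the
#' mean of the per-replicate ratios, with their standard deviation as the
#' spread. The standard design is 3 replicates of 10 grains each.
#'
#' @param measurements Tidy data frame with columns `replicate`, `state`
#'   (`"cooked"` or `"milled"`) and `length_mm` (> 0).
#' @return One-row tibble: `ge_ratio`, `sd`, `n_replicates`.
#' @examples
#' ge_ratio(data.frame(replicate = rep(1:3, each = 2),
#'                     state = rep(c("cooked", "milled"), 3),
#'                     length_mm = rep(c(14.5, 6.4), 3)))
#' @export
ge_ratio <- function(measurements) {
  need <- c("replicate", "state", "length_mm")
  if (!all(need %in% names(measurements))) {
    abort("ge_ratio: need columns replicate, state, length_mm")
  }
  if (any(measurements$length_mm <= 0 | !is.finite(measurements$length_mm))) {
    abort("ge_ratio: grain lengths must be positive")
  }
  if (!all(measurements$state %in% c("cooked", "milled"))) {
    abort("ge_ratio: state must be 'cooked' or 'milled'")
  }
  per_rep <- measurements |>
    dplyr::group_by(.data$replicate, .data$state) |>
    dplyr::summarise(mean_len = mean(.data$length_mm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "state", values_from = "mean_len")
  if (!all(c("cooked", "milled") %in% names(per_rep)) ||
      anyNA(per_rep$cooked) || anyNA(per_rep$milled)) {
    abort("ge_ratio: every replicate needs both cooked and milled grains")
  }
  ratios <- per_rep$cooked / per_rep$milled
  tibble(ge_ratio = mean(ratios),
         sd = if (length(ratios) > 1) stats::sd(ratios) else 0,
         n_replicates = length(ratios))
}
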