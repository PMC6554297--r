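#' Plot a delta(SNP index) genome scan
#'
#' Per-SNP delta values with the sliding-window mean and the null
#' confidence bounds at the scan's calling level, faceted by chromosome.
#' Called regions, if any, are shaded.
#'
#' @param object A `bsa_scan` from [run_bsa_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsa_scan <- function(object, ...) {
  lev <- object$params$level
  ci_lev <- object$ci[abs(object$ci$level - lev) < 1e-9, ]
  bounds <- object$windows |>
    dplyr::filter(!is.na(.data$mean_depth)) |>
    dplyr::mutate(
      bound = ci_lev$upper[match(nearest_match(round(.data$mean_depth),
                                               ci_lev$depth),
                                 ci_lev$depth)])
  p <- ggplot2::ggplot(object$snps,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$delta)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6, colour = "grey40")
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.2)
  }
  p +
    ggplot2::geom_line(data = bounds,
                       ggplot2::aes(x = .data$window_start / 1e6,
                                    y = .data$bound),
                       linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_line(data = bounds,
                       ggplot2::aes(x = .data$window_start / 1e6,
                                    y = -.data$bound),
                       linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_line(
      data = dplyr::filter(object$windows, !is.na(.data$mean_delta)),
      ggplot2::aes(x = .data$window_start / 1e6, y = .data$mean_delta),
      colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta * "(SNP index)"),
                  title = paste0("delta(SNP index) scan (", lev * 100,
                                 "% null bounds)")) +
    ggplot2::theme_minimal()
}

#' Plot a simulated null delta distribution
#'
#' Histogram of the Monte-Carlo null delta sample per depth, with the
#' two-sided 95% and 99% bounds marked.
#'
#' @param object A `bsa_null` from [null_delta_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsa_null <- function(object, ...) {
  df <- purrr::imap(object$samples,
                    \(s, d) tibble(depth = d, delta = s)) |>
    purrr::list_rbind()
  ci <- ci_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(data = as_tibble(ci),
                        ggplot2::aes(xintercept = .data$upper,
                                     colour = factor(.data$level)),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = as_tibble(ci),
                        ggplot2::aes(xintercept = .data$lower,
                                     colour = factor(.data$level)),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~depth, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(Delta * "(SNP index)"), y = "replicates",
                  colour = "level",
                  title = paste0("Null delta(SNP index), bulk size ",
                                 object$bulk_size)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
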