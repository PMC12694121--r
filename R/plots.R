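#' Genome-wide Delta(SNP-index) plot
#'
#' Per-site Delta with the windowed means overlaid, facetted by chromosome.
#'
#' @param result A `bsa_scan_result`.
#' @return A ggplot object.
#' @export
plot_delta_scan <- function(result) {
  ggplot2::ggplot(result$scan,
                  ggplot2::aes(x = .data$pos / 1e6, y = .data$delta)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6, colour = "grey40") +
    ggplot2::geom_segment(
      data = result$delta_windows,
      ggplot2::aes(x = .data$window_start / 1e6,
                   xend = .data$window_end / 1e6,
                   y = .data$mean_delta, yend = .data$mean_delta),
      colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta * "(SNP-index)"),
                  title = "Delta(SNP-index) scan") +
    ggplot2::theme_minimal()
}

#' Genome-wide Euclidean-distance plot
#'
#' Raw per-site ED with the fitted curve and the median + k SD association
#' threshold, facetted by chromosome.
#'
#' @param result A `bsa_scan_result`.
#' @return A ggplot object.
#' @export
plot_ed_scan <- function(result) {
  ggplot2::ggplot(result$fitted,
                  ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ed), alpha = 0.3,
                        size = 0.6, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_ed),
                       colour = "steelblue", linewidth = 0.9) +
    ggplot2::geom_hline(yintercept = result$ed_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "Euclidean distance",
                  title = "ED scan (dashed: median + k SD threshold)") +
    ggplot2::theme_minimal()
}

#' KASP genotype-cluster plot
#'
#' Two-channel fluorescence scatter coloured by genotype call.
#'
#' @param calls Tibble from [call_genotypes()].
#' @return A ggplot object.
#' @export
plot_genotype_clusters <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$fam, y = .data$hex,
                                      colour = .data$call)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "FAM signal", y = "HEX signal",
                  title = "KASP genotype clusters") +
    ggplot2::theme_minimal()
}
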