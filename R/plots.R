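#' Plot the ROH length-class distribution
#'
#' @param class_summary a [summarize_classes()] tibble.
#' @return A ggplot.
#' @export
plot_class_summary <- function(class_summary) {
  ggplot2::ggplot(class_summary,
                  ggplot2::aes(x = .data$length_class, y = 100 * .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "ROH class (Mb)", y = "% of ROH segments") +
    ggplot2::theme_minimal()
}

#' Plot per-individual ROH burden
#'
#' Scatter of segment count against total ROH length per individual.
#'
#' @param individual_summary a [summarize_individuals()] tibble.
#' @return A ggplot.
#' @export
plot_individual_summary <- function(individual_summary) {
  ggplot2::ggplot(individual_summary,
                  ggplot2::aes(x = .data$total_length_mb, y = .data$n_segments)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Total ROH length (Mb)", y = "Number of ROH segments") +
    ggplot2::theme_minimal()
}

#' Plot the per-chromosome ROH distribution
#'
#' Bars give segment counts; the line the percentage of all ROH.
#'
#' @param chrom_summary a [summarize_chromosomes()] tibble.
#' @return A ggplot.
#' @export
plot_chromosome_summary <- function(chrom_summary) {
  chrom_summary$chromosome <- factor(chrom_summary$chromosome,
                                     levels = chrom_summary$chromosome)
  scale <- max(chrom_summary$n, 1) / max(chrom_summary$pct_of_all, 1)
  ggplot2::ggplot(chrom_summary, ggplot2::aes(x = .data$chromosome)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pct_of_all * scale, group = 1),
                       colour = "firebrick") +
    ggplot2::scale_y_continuous(
      name = "Number of ROH",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "% of ROH")
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-generation trends of the inbreeding estimators
#'
#' @param trend a [generation_trend()] tibble.
#' @param group the grouping column name (default `"generation"`).
#' @return A ggplot.
#' @export
plot_generation_trend <- function(trend, group = "generation") {
  long <- tidyr::pivot_longer(trend, -dplyr::all_of(group),
                              names_to = "estimator", values_to = "mean_f")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group]], y = .data$mean_f,
                                     colour = .data$estimator,
                                     group = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "Mean inbreeding coefficient") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of per-SNP ROH incidence
#'
#' @param track a [snp_incidence()] tibble.
#' @param quantile threshold quantile drawn as a horizontal line (default
#'   0.999).
#' @return A ggplot.
#' @export
plot_incidence <- function(track, quantile = 0.999) {
  thr <- island_threshold(track, quantile)
  n_ind <- attr(track, "n_individuals")
  track$chromosome <- factor(track$chromosome, levels = unique(track$chromosome))
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$position_bp / 1e6,
                                           y = 100 * .data$proportion,
                                           colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
    ggplot2::facet_grid(~ .data$chromosome, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "% of individuals with SNP in ROH") +
    ggplot2::theme_minimal()
  if (is.finite(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = 100 * thr / n_ind,
                                 colour = "red", linetype = 2)
  }
  p
}

#' @export
#' @method autoplot estimator_correlations
autoplot.estimator_correlations <- function(object, ...) {
  long <- tidy.estimator_correlations(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimator1, y = .data$estimator2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
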