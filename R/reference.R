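#' Published ROH summary for the red-brown Korean native chicken
#'
#' Reference summary statistics from a published 60K-chip study of 651
#' red-brown Korean native chickens sampled over four generations
#' (2019-2022). The underlying genotypes are not public, so these printed
#' summaries are the only reference surface: the per-class segment table
#' and the headline population statistics. They are used by
#' [consistency_checks()] to verify that the study's headline numbers are
#' mutually consistent under this package's definitions.
#'
#' @return `ref_class_summary()`: a tibble (`length_class`, `n`,
#'   `frequency`, `mean_length_mb`) of the published per-class segment
#'   table.
#' @export
ref_class_summary <- function() {
  tibble::tibble(
    length_class = factor(c("1-2", "2-4", "4-8", "8-16", ">16"),
                          levels = c("1-2", "2-4", "4-8", "8-16", ">16")),
    n = c(16414L, 10566L, 4110L, 981L, 105L),
    frequency = c(0.511, 0.327, 0.128, 0.032, 0.003),
    mean_length_mb = c(1.441, 2.732, 5.504, 10.267, 20.085)
  )
}

#' @rdname ref_class_summary
#' @return `ref_study_stats()`: a list of headline statistics —
#'   `n_individuals`, `n_segments`, `mean_segments_per_bird`,
#'   `mean_segment_length_mb`, `mean_total_roh_mb`, `mean_f_roh`,
#'   `genome_length_bp`, `n_snps_chip`, `n_snps_roh`, `n_snps_estimators`,
#'   and the per-generation sample sizes `generation_sizes`.
#' @export
ref_study_stats <- function() {
  list(
    n_individuals = 651L,
    n_segments = 32176L,
    mean_segments_per_bird = 49,
    mean_segment_length_mb = 2.7,
    mean_total_roh_mb = 134.12,
    mean_f_roh = 0.143,
    genome_length_bp = 0.94e9,
    n_snps_chip = 57636L,
    n_snps_roh = 53872L,
    n_snps_estimators = 44569L,
    generation_sizes = c(`2019` = 158L, `2020` = 193L, `2021` = 100L,
                         `2022` = 200L)
  )
}

#' Internal-consistency checks on the published summaries
#'
#' Recomputes three headline quantities from the published inputs they are
#' derived from, using this package's own formulas:
#' the mean `F_ROH` from the mean total ROH length and the autosomal genome
#' length (via [f_roh()]); the mean number of segments per bird from the
#' total segment count and sample size; and the overall mean segment length
#' as the count-weighted mean of the per-class means (via
#' [overall_mean_from_classes()]).
#'
#' @return A tibble: `quantity`, `derived`, `published`.
#' @export
consistency_checks <- function() {
  stats <- ref_study_stats()
  classes <- ref_class_summary()

  mean_froh <- f_roh(
    tibble::tibble(individual_id = "population_mean",
                   length_bp = stats$mean_total_roh_mb * 1e6),
    l_auto = stats$genome_length_bp
  )$f_roh

  tibble::tibble(
    quantity = c("mean_f_roh", "mean_segments_per_bird",
                 "mean_segment_length_mb"),
    derived = c(
      mean_froh,
      stats$n_segments / stats$n_individuals,
      overall_mean_from_classes(classes)
    ),
    published = c(stats$mean_f_roh, stats$mean_segments_per_bird,
                  stats$mean_segment_length_mb)
  )
}
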