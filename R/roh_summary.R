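#' Summarize ROH segments by length class
#'
#' One row per length class (empty classes kept with zero counts):
#' segment count, frequency among all segments, and mean length in Mb.
#'
#' @param segments a [detect_roh()] result (or any tibble with `length_bp`).
#' @return A tibble: `length_class`, `n`, `frequency`, `mean_length_mb`.
#' @export
summarize_classes <- function(segments) {
  cls <- segments$length_class %||% roh_length_class(segments$length_bp)
  total <- length(cls)
  by_class <- tibble::tibble(length_class = cls, length_bp = segments$length_bp) |>
    dplyr::group_by(.data$length_class, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_length_mb = mean(.data$length_bp) / 1e6,
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$length_class))
  by_class$frequency <- if (total > 0) by_class$n / total else 0
  by_class$mean_length_mb[by_class$n == 0] <- NA_real_
  by_class[, c("length_class", "n", "frequency", "mean_length_mb")]
}

#' Count-weighted overall mean length from a class summary
#'
#' Recombines per-class counts and mean lengths into the overall mean
#' segment length — the internal-consistency relation between a class table
#' and the headline mean.
#'
#' @param class_summary a tibble with columns `n` and `mean_length_mb`.
#' @return Overall mean segment length in Mb.
#' @export
overall_mean_from_classes <- function(class_summary) {
  ok <- class_summary$n > 0
  sum(class_summary$n[ok] * class_summary$mean_length_mb[ok]) /
    sum(class_summary$n[ok])
}

#' Per-individual ROH burden
#'
#' Segment count, total and mean length per individual. Individuals present
#' in `samples` but without segments are reported with zeros, so population
#' means are not inflated.
#'
#' @param segments a [detect_roh()] result.
#' @param samples optional sample table (`individual_id`, ...) defining the
#'   full individual set.
#' @return A tibble: `individual_id`, `n_segments`, `total_length_mb`,
#'   `mean_length_mb`.
#' @export
summarize_individuals <- function(segments, samples = NULL) {
  per <- segments |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      total_length_mb = sum(.data$length_bp) / 1e6,
      .groups = "drop"
    )
  if (!is.null(samples)) {
    per <- dplyr::left_join(
      tibble::tibble(individual_id = samples$individual_id), per,
      by = "individual_id"
    )
    per$n_segments[is.na(per$n_segments)] <- 0L
    per$total_length_mb[is.na(per$total_length_mb)] <- 0
  }
  per$mean_length_mb <- ifelse(per$n_segments > 0,
                               per$total_length_mb / per$n_segments, 0)
  per
}

#' Per-chromosome ROH distribution
#'
#' @param segments a [detect_roh()] result.
#' @param chromosomes optional character vector (or a `recomb_map`) naming
#'   every chromosome, so chromosomes without segments appear with zeros.
#' @return A tibble: `chromosome`, `n`, `pct_of_all`, `mean_length_mb`.
#' @export
summarize_chromosomes <- function(segments, chromosomes = NULL) {
  if (inherits(chromosomes, "recomb_map")) chromosomes <- chromosomes$chrom$chromosome
  chromosomes <- chromosomes %||% unique(segments$chromosome)
  per <- segments |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_length_mb = mean(.data$length_bp) / 1e6,
      .groups = "drop"
    )
  out <- dplyr::left_join(tibble::tibble(chromosome = as.character(chromosomes)),
                          per, by = "chromosome")
  out$n[is.na(out$n)] <- 0L
  out$pct_of_all <- if (sum(out$n) > 0) 100 * out$n / sum(out$n) else 0
  out[, c("chromosome", "n", "pct_of_all", "mean_length_mb")]
}

#' ROH class composition per cohort
#'
#' Class frequency vectors per group (e.g. generation); each group's
#' frequencies sum to 1.
#'
#' @param segments a [detect_roh()] result.
#' @param samples sample table with `individual_id` and the grouping column.
#' @param group name of the grouping column (default `"generation"`).
#' @return A tibble: group, `length_class`, `n`, `frequency`.
#' @export
summarize_by_group <- function(segments, samples, group = "generation") {
  if (!group %in% names(samples)) {
    abort(sprintf("column `%s` not found in samples", group))
  }
  unknown <- setdiff(segments$individual_id, samples$individual_id)
  if (length(unknown)) {
    abort(sprintf("segments refer to %d individual(s) absent from samples",
                  length(unknown)))
  }
  joined <- dplyr::left_join(
    tibble::as_tibble(segments),
    samples[, c("individual_id", group)],
    by = "individual_id"
  )
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group)), .data$length_class,
                    .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::filter(!is.na(.data$length_class)) |>
    dplyr::mutate(frequency = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0) |>
    dplyr::ungroup()
}
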