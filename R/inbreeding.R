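#' Allele frequencies from the current sample
#'
#' Frequency of allele A1 per marker, from non-missing calls only.
#'
#' @param gm a [genotypes()] object.
#' @return Numeric vector of length `n_markers(gm)`.
#' @export
allele_freqs <- function(gm) {
  nonmiss <- colSums(!is.na(gm$calls))
  ifelse(nonmiss > 0, colSums(gm$calls, na.rm = TRUE) / (2 * nonmiss), NA_real_)
}

#' ROH-based inbreeding coefficient
#'
#' F_ROH: the summed length of an individual's ROH segments divided by the
#' autosomal genome length. Also computed per length class when
#' `by_class = TRUE`; class values over disjoint classes sum to the overall
#' coefficient for each individual.
#'
#' @param segments a [detect_roh()] result.
#' @param l_auto autosomal genome length in bp (default `0.94e9`).
#' @param individuals optional character vector (or sample table) naming
#'   every individual, so individuals without segments get `f_roh = 0`.
#' @param by_class also return per-class columns `f_roh_1_2`, `f_roh_2_4`,
#'   `f_roh_4_8`, `f_roh_8_16`, `f_roh_gt16`.
#' @return A tibble with `individual_id` and `f_roh` (plus class columns).
#' @export
f_roh <- function(segments, l_auto = 0.94e9, individuals = NULL,
                  by_class = FALSE) {
  if (l_auto <= 0) abort("l_auto must be positive")
  if (any(segments$length_bp < 0)) abort("negative segment length")
  if (is.data.frame(individuals)) individuals <- individuals$individual_id
  individuals <- individuals %||% unique(segments$individual_id)

  overall <- segments |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(f_roh = sum(.data$length_bp) / l_auto, .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(individual_id = individuals),
                          overall, by = "individual_id")
  out$f_roh[is.na(out$f_roh)] <- 0

  if (by_class) {
    cls <- segments$length_class %||% roh_length_class(segments$length_bp)
    wide <- tibble::tibble(
      individual_id = segments$individual_id,
      length_class = cls, length_bp = segments$length_bp
    ) |>
      dplyr::filter(!is.na(.data$length_class)) |>
      dplyr::group_by(.data$individual_id, .data$length_class, .drop = FALSE) |>
      dplyr::summarise(f = sum(.data$length_bp) / l_auto, .groups = "drop") |>
      tidyr::pivot_wider(names_from = "length_class", values_from = "f",
                         values_fill = 0)
    names(wide) <- sub("^>16$", "f_roh_gt16", names(wide))
    names(wide) <- sub("^(\\d+)-(\\d+)$", "f_roh_\\1_\\2", names(wide))
    out <- dplyr::left_join(out, wide, by = "individual_id")
    class_cols <- c("f_roh_1_2", "f_roh_2_4", "f_roh_4_8", "f_roh_8_16",
                    "f_roh_gt16")
    for (cc in setdiff(class_cols, names(out))) out[[cc]] <- 0
    out <- out[, c("individual_id", "f_roh", class_cols)]
    for (cc in class_cols) out[[cc]][is.na(out[[cc]])] <- 0
  }
  out
}

# per-individual helper shared by the SNP-by-SNP estimators: drops
# monomorphic markers and handles missing calls individual-by-individual
snp_estimator_setup <- function(gm, freqs) {
  p <- freqs %||% allele_freqs(gm)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) abort("all markers are monomorphic: estimator undefined")
  list(p = p[poly], calls = gm$calls[, poly, drop = FALSE])
}

#' GRM-diagonal inbreeding coefficient
#'
#' F_GRM: inbreeding from the diagonal of a VanRaden genomic relationship
#' matrix on frequency-centred genotypes. The default `ratio_of_sums`
#' variant is \eqn{\sum_j (x_{ij} - 2p_j)^2 / (2\sum_j p_j q_j) - 1};
#' `mean_of_ratios` averages the per-SNP ratios instead. Monomorphic
#' markers are excluded; missing calls are excluded from both numerator and
#' denominator of that individual.
#'
#' @param gm a [genotypes()] object (apply a MAF filter first if desired).
#' @param variant `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @param freqs optional allele frequencies (default: from the sample).
#' @return A tibble with `individual_id` and `f_grm`.
#' @export
f_grm <- function(gm, variant = c("ratio_of_sums", "mean_of_ratios"),
                  freqs = NULL) {
  variant <- match.arg(variant)
  su <- snp_estimator_setup(gm, freqs)
  p <- su$p
  x <- su$calls
  ctr <- sweep(x, 2, 2 * p)        # x - 2p, NA where missing
  pq2 <- 2 * p * (1 - p)
  if (variant == "ratio_of_sums") {
    num <- rowSums(ctr^2, na.rm = TRUE)
    den <- (!is.na(x)) %*% pq2
    f <- num / as.vector(den) - 1
  } else {
    ratio <- sweep(ctr^2, 2, pq2, "/")
    f <- rowMeans(ratio, na.rm = TRUE) - 1
  }
  tibble::tibble(individual_id = gm$samples$individual_id, f_grm = unname(f))
}

#' Excess-homozygosity inbreeding coefficient
#'
#' F_HOM: (observed - expected homozygous loci) / (non-missing loci -
#' expected homozygous loci), with the expectation
#' \eqn{\sum_j (1 - 2 p_j q_j)} over the individual's non-missing markers.
#' Equals 1 exactly for a fully homozygous individual; degenerate
#' individuals (denominator 0) get `NA` with a warning.
#'
#' @inheritParams f_grm
#' @return A tibble with `individual_id` and `f_hom`.
#' @export
f_hom <- function(gm, freqs = NULL) {
  su <- snp_estimator_setup(gm, freqs)
  p <- su$p
  x <- su$calls
  obs_nonmiss <- !is.na(x)
  L <- rowSums(obs_nonmiss)
  o_hom <- rowSums(x != 1L, na.rm = TRUE)
  e_hom <- as.vector(obs_nonmiss %*% (1 - 2 * p * (1 - p)))
  den <- L - e_hom
  f <- ifelse(abs(den) < 1e-12, NA_real_, (o_hom - e_hom) / den)
  if (anyNA(f)) warn(sprintf("%d individual(s) with degenerate F_HOM (denominator 0)",
                             sum(is.na(f))))
  tibble::tibble(individual_id = gm$samples$individual_id, f_hom = unname(f))
}

#' Uniting-gametes inbreeding coefficient
#'
#' F_UNI: the correlation between alleles in uniting gametes, averaged
#' per SNP: \eqn{\frac{1}{n}\sum_m \frac{x_m^2 - (1 + 2p_m) x_m + 2p_m^2}
#' {2 p_m q_m}} over the individual's non-missing polymorphic markers.
#'
#' @inheritParams f_grm
#' @return A tibble with `individual_id` and `f_uni`.
#' @export
f_uni <- function(gm, freqs = NULL) {
  su <- snp_estimator_setup(gm, freqs)
  p <- su$p
  x <- su$calls
  num <- x^2 - sweep(x, 2, 1 + 2 * p, "*") + matrix(2 * p^2, nrow(x), ncol(x),
                                                    byrow = TRUE)
  term <- sweep(num, 2, 2 * p * (1 - p), "/")
  f <- rowMeans(term, na.rm = TRUE)
  tibble::tibble(individual_id = gm$samples$individual_id, f_uni = unname(f))
}

#' All four genomic inbreeding coefficients
#'
#' Per-individual F_ROH (overall and per length class), F_GRM, F_HOM and
#' F_UNI. A MAF filter (`min_maf`, default 0.05) is applied to the
#' genotypes before the three SNP-by-SNP estimators but never before
#' F_ROH, which only consumes the called segments.
#'
#' @param gm a [genotypes()] object (post-QC, no MAF filter).
#' @param segments a [detect_roh()] result for the same individuals.
#' @param l_auto autosomal genome length in bp (default `0.94e9`).
#' @param min_maf MAF threshold for the SNP-by-SNP estimators (default
#'   0.05; `NULL` disables).
#' @param grm_variant passed to [f_grm()].
#' @return A tibble of class `inbreeding_records`: one row per individual,
#'   columns `individual_id`, `f_roh`, the five class columns, `f_grm`,
#'   `f_hom`, `f_uni`.
#' @export
compute_inbreeding <- function(gm, segments, l_auto = 0.94e9, min_maf = 0.05,
                               grm_variant = "ratio_of_sums") {
  gm_est <- gm
  if (!is.null(min_maf)) {
    if (!"maf" %in% names(gm_est$markers)) gm_est <- compute_marker_stats(gm_est)
    gm_est <- gm_est[, which(!is.na(gm_est$markers$maf) &
                               gm_est$markers$maf >= min_maf)]
  }
  out <- f_roh(segments, l_auto = l_auto, individuals = gm$samples,
               by_class = TRUE)
  out <- out |>
    dplyr::left_join(f_grm(gm_est, variant = grm_variant), by = "individual_id") |>
    dplyr::left_join(f_hom(gm_est), by = "individual_id") |>
    dplyr::left_join(f_uni(gm_est), by = "individual_id")
  class(out) <- c("inbreeding_records", class(tibble::tibble()))
  out
}

#' Pearson correlations among inbreeding estimators
#'
#' Pairwise Pearson correlation over every coefficient column, using
#' pairwise-complete observations. Zero-variance columns give `NA`
#' correlations with a warning.
#'
#' @param records a [compute_inbreeding()] tibble (or any tibble of
#'   `individual_id` plus numeric coefficient columns).
#' @return A correlation matrix of class `estimator_correlations`.
#' @export
estimator_correlations <- function(records) {
  num <- records[, vapply(records, is.numeric, logical(1)), drop = FALSE]
  if (nrow(num) < 3) abort("need at least 3 individuals for correlations")
  sds <- vapply(num, function(v) sd(v, na.rm = TRUE), numeric(1))
  if (any(!is.na(sds) & sds == 0)) {
    warn(sprintf("zero-variance column(s): %s",
                 paste(names(num)[!is.na(sds) & sds == 0], collapse = ", ")))
  }
  r <- suppressWarnings(cor(as.matrix(num), use = "pairwise.complete.obs",
                            method = "pearson"))
  structure(r, class = c("estimator_correlations", "matrix"))
}

#' @export
#' @method tidy estimator_correlations
tidy.estimator_correlations <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    estimator1 = rep(rownames(m), times = ncol(m)),
    estimator2 = rep(colnames(m), each = nrow(m)),
    r = as.vector(m)
  )
}

#' @export
#' @method glance estimator_correlations
glance.estimator_correlations <- function(x, ...) {
  m <- unclass(x)
  off <- m[lower.tri(m)]
  tibble::tibble(
    n_estimators = ncol(m),
    min_r = min(off, na.rm = TRUE),
    max_r = max(off, na.rm = TRUE)
  )
}

#' @export
print.estimator_correlations <- function(x, ...) {
  cat("<estimator_correlations>\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-generation means of the inbreeding estimators
#'
#' @param records a [compute_inbreeding()] tibble.
#' @param samples sample table with `individual_id` and the grouping column.
#' @param group grouping column name (default `"generation"`).
#' @return A tibble: group column, then the mean of every coefficient.
#' @export
generation_trend <- function(records, samples, group = "generation") {
  if (!group %in% names(samples)) {
    abort(sprintf("column `%s` not found in samples", group))
  }
  dplyr::left_join(tibble::as_tibble(records),
                   samples[, c("individual_id", group)],
                   by = "individual_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(group)))
}
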