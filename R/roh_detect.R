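#' Sliding-window ROH calling parameters
#'
#' Defaults follow a common 60K-chip parameterization of the PLINK
#' `--homozyg` scan: 49-SNP windows allowing 1 heterozygous and 5 missing
#' calls, window hit-ratio threshold 0.05, a maximum gap of 1,500 kb
#' between consecutive SNPs in a run, and a minimum segment length of
#' 1,000 kb.
#'
#' @param window_snps sliding-window size in SNPs (default 49; see
#'   [min_window_snps()] for the false-positive-rate derivation).
#' @param window_het_max maximum heterozygous calls per window (default 1).
#' @param window_missing_max maximum missing calls per window (default 5).
#' @param window_threshold minimum fraction of qualifying windows covering
#'   a SNP for it to enter a run (default 0.05).
#' @param max_gap_kb split a run where consecutive SNPs are farther apart
#'   than this (default 1500).
#' @param min_length_kb minimum emitted segment length (default 1000).
#' @param min_snps minimum SNPs per emitted segment (default: `window_snps`).
#' @param max_het_per_segment optional strict cap on heterozygous calls in
#'   the final segment (default `NULL`: window-level allowance only, the
#'   PLINK semantics).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 49, window_het_max = 1,
                       window_missing_max = 5, window_threshold = 0.05,
                       max_gap_kb = 1500, min_length_kb = 1000,
                       min_snps = window_snps, max_het_per_segment = NULL) {
  if (window_snps < 1) abort("window_snps must be >= 1")
  if (window_threshold <= 0 || window_threshold > 1) {
    abort("window_threshold must be in (0, 1]")
  }
  if (min_length_kb <= 0) abort("min_length_kb must be positive")
  structure(
    list(window_snps = as.integer(window_snps),
         window_het_max = as.integer(window_het_max),
         window_missing_max = as.integer(window_missing_max),
         window_threshold = window_threshold,
         max_gap_kb = max_gap_kb, min_length_kb = min_length_kb,
         min_snps = as.integer(min_snps),
         max_het_per_segment = max_het_per_segment),
    class = "roh_params"
  )
}

#' Minimum sliding-window size for ROH detection
#'
#' The Lencz false-positive bound: the smallest window (in SNPs) such that
#' the expected number of chance all-homozygous windows across the dataset
#' stays below `alpha`:
#' \deqn{L = \frac{\ln(\alpha / (n_s n_i))}{\ln(1 - het)}}
#' rounded half-up to the nearest integer and floored at 1.
#'
#' @param n_snps genotyped SNPs per individual.
#' @param n_individuals genotyped individuals.
#' @param mean_het average heterozygosity across genotyped SNPs, in (0, 1).
#' @param alpha tolerated false-positive proportion (default 0.05).
#' @return Integer window size.
#' @export
#' @examples
#' min_window_snps(n_snps = 53872, n_individuals = 651, mean_het = 0.34)
min_window_snps <- function(n_snps, n_individuals, mean_het, alpha = 0.05) {
  stopifnot_scalar_count(n_snps, "n_snps")
  stopifnot_scalar_count(n_individuals, "n_individuals")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (mean_het <= 0 || mean_het >= 1) abort("mean_het must be in (0, 1)")
  L <- log(alpha / (n_snps * n_individuals)) / log(1 - mean_het)
  max(1L, as.integer(round_half_up(L)))
}

#' Detect runs of homozygosity
#'
#' PLINK-style sliding-window scan, per individual and chromosome:
#' every contiguous window of `window_snps` markers qualifies if it holds
#' at most `window_het_max` heterozygous and `window_missing_max` missing
#' calls; each marker's hit ratio is the fraction of windows containing it
#' (fully on the chromosome) that qualify; markers at hit ratio >=
#' `window_threshold` form candidate runs of consecutive markers; runs are
#' split across gaps larger than `max_gap_kb`; runs shorter than
#' `min_length_kb` or with fewer than `min_snps` markers are dropped.
#' Chromosomes with fewer markers than the window yield no calls.
#'
#' Markers must be sorted by chromosome and position (see [sort_markers()]);
#' run quality control first — conventionally with no MAF filter, so that
#' fixed and near-fixed sites can support long runs.
#'
#' @param gm a [genotypes()] object.
#' @param params a [roh_params()] list.
#' @return A tibble of class `roh_segments`: `individual_id`, `chromosome`,
#'   `start_bp`, `end_bp` (positions of the first and last marker in the
#'   run), `n_snps`, `length_bp` (`end_bp - start_bp`), `length_class`.
#'   The parameter set is attached as attribute `params`.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  if (!markers_sorted(gm)) {
    abort("markers are not sorted by position within chromosomes; see sort_markers()")
  }
  W <- params$window_snps
  H <- params$window_het_max
  M <- params$window_missing_max
  Tthr <- params$window_threshold
  gap_bp <- params$max_gap_kb * 1000
  min_bp <- params$min_length_kb * 1000

  markers <- gm$markers
  chrom_cols <- split(seq_len(n_markers(gm)),
                      factor(markers$chromosome, levels = unique(markers$chromosome)))
  out <- list()
  for (chr in names(chrom_cols)) {
    cols <- chrom_cols[[chr]]
    m <- length(cols)
    if (m < W) next
    pos <- markers$position_bp[cols]
    nwin <- m - W + 1L
    i_seq <- seq_len(m)
    lo_w <- pmax(1L, i_seq - W + 1L)
    hi_w <- pmin(i_seq, nwin)
    ntot <- hi_w - lo_w + 1L
    gap_break <- c(FALSE, diff(pos) > gap_bp)

    for (s in seq_len(n_samples(gm))) {
      g <- gm$calls[s, cols]
      mis <- is.na(g)
      het <- !mis & g == 1L
      cs_h <- c(0L, cumsum(het))
      cs_m <- c(0L, cumsum(mis))
      qual <- (cs_h[i_seq[1:nwin] + W] - cs_h[1:nwin]) <= H &
        (cs_m[i_seq[1:nwin] + W] - cs_m[1:nwin]) <= M
      if (!any(qual)) next
      cq <- c(0L, cumsum(qual))
      nq <- cq[hi_w + 1L] - cq[lo_w]
      cand <- (nq / ntot) >= Tthr
      if (!any(cand)) next

      # runs of consecutive candidate markers, split at large gaps
      run_id <- cumsum(!cand | gap_break)
      idx <- which(cand)
      runs <- split(idx, run_id[idx])
      for (r in runs) {
        first <- r[1]
        last <- r[length(r)]
        len <- pos[last] - pos[first]
        if (len < min_bp || length(r) < params$min_snps) next
        if (!is.null(params$max_het_per_segment) &&
            sum(het[first:last]) > params$max_het_per_segment) next
        out[[length(out) + 1L]] <- list(
          individual_id = gm$samples$individual_id[s],
          chromosome = chr,
          start_bp = pos[first], end_bp = pos[last],
          n_snps = length(r), length_bp = len
        )
      }
    }
  }
  segs <- if (length(out)) {
    dplyr::bind_rows(lapply(out, tibble::as_tibble))
  } else {
    tibble::tibble(individual_id = character(), chromosome = character(),
                   start_bp = integer(), end_bp = integer(),
                   n_snps = integer(), length_bp = integer())
  }
  segs$length_class <- roh_length_class(segs$length_bp)
  attr(segs, "params") <- params
  class(segs) <- c("roh_segments", class(tibble::tibble()))
  segs
}

#' ROH length classes
#'
#' Bins segment lengths into the conventional classes 1-2, 2-4, 4-8, 8-16
#' and >16 Mb (left-closed, right-open). Lengths below 1 Mb get `NA`.
#'
#' @param length_bp numeric vector of segment lengths in base pairs.
#' @return A factor with levels `"1-2"`, `"2-4"`, `"4-8"`, `"8-16"`, `">16"`.
#' @export
roh_length_class <- function(length_bp) {
  cut(length_bp / 1e6, breaks = c(1, 2, 4, 8, 16, Inf), right = FALSE,
      labels = c("1-2", "2-4", "4-8", "8-16", ">16"))
}

#' @export
#' @method glance roh_segments
glance.roh_segments <- function(x, ...) {
  tibble::tibble(
    n_segments = nrow(x),
    n_individuals = dplyr::n_distinct(x$individual_id),
    total_length_mb = sum(x$length_bp) / 1e6,
    mean_length_mb = if (nrow(x)) mean(x$length_bp) / 1e6 else NA_real_,
    max_length_mb = if (nrow(x)) max(x$length_bp) / 1e6 else NA_real_
  )
}
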