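#' Per-SNP ROH incidence across the population
#'
#' Counts, for every marker, how many individuals have an ROH segment
#' covering its position (each individual at most once per marker), the
#' corresponding population proportion, and the genome-wide Z-score of the
#' counts.
#'
#' @param segments a [detect_roh()] result.
#' @param gm the [genotypes()] object the segments were called from (its
#'   marker map defines the positions; its sample count the denominator).
#' @return A tibble of class `roh_incidence`: `chromosome`, `marker_id`,
#'   `position_bp`, `n_roh`, `proportion`, `z`. The number of individuals
#'   is attached as attribute `n_individuals`.
#' @export
snp_incidence <- function(segments, gm) {
  markers <- gm$markers
  n_ind <- n_samples(gm)
  counts <- integer(nrow(markers))
  for (chr in unique(markers$chromosome)) {
    rows <- which(markers$chromosome == chr)
    pos <- markers$position_bp[rows]
    segs <- segments[segments$chromosome == chr, , drop = FALSE]
    if (!nrow(segs)) next
    # one individual's segments never overlap, so each covering segment
    # contributes one distinct individual at a marker
    delta <- integer(length(rows) + 1L)
    i1 <- findInterval(segs$start_bp - 1L, pos) + 1L  # first marker >= start
    i2 <- findInterval(segs$end_bp, pos)              # last marker <= end
    ok <- i1 <= i2
    for (k in which(ok)) {
      delta[i1[k]] <- delta[i1[k]] + 1L
      delta[i2[k] + 1L] <- delta[i2[k] + 1L] - 1L
    }
    counts[rows] <- cumsum(delta[-length(delta)])
  }
  mu <- mean(counts)
  s <- sd(counts)
  out <- tibble::tibble(
    chromosome = markers$chromosome,
    marker_id = markers$marker_id,
    position_bp = markers$position_bp,
    n_roh = counts,
    proportion = counts / n_ind,
    z = if (is.na(s) || s == 0) NA_real_ else (counts - mu) / s
  )
  attr(out, "n_individuals") <- n_ind
  class(out) <- c("roh_incidence", class(tibble::tibble()))
  out
}

#' Incidence threshold for ROH islands
#'
#' The count above which a marker belongs to the top 0.1% of the incidence
#' distribution. With `method = "zscore"` (default) the counts are
#' standardized and a marker qualifies when its upper-tail standard-normal
#' probability exceeds `quantile`, i.e. `z > qnorm(quantile)` (3.0902 at
#' 0.999); `method = "empirical"` uses the empirical count quantile
#' instead, which differs when the incidence distribution is skewed.
#'
#' @param track a [snp_incidence()] tibble.
#' @param quantile upper-tail quantile (default 0.999, the top 0.1%).
#' @param method `"zscore"` or `"empirical"`.
#' @return The count threshold (markers qualify strictly above it). `Inf`
#'   with a warning when the incidence track has zero variance.
#' @export
island_threshold <- function(track, quantile = 0.999,
                             method = c("zscore", "empirical")) {
  method <- match.arg(method)
  s <- sd(track$n_roh)
  if (is.na(s) || s == 0) {
    warn("incidence has zero variance: no island threshold")
    return(Inf)
  }
  if (method == "zscore") {
    mean(track$n_roh) + qnorm(quantile) * s
  } else {
    as.numeric(quantile(track$n_roh, probs = quantile, type = 7))
  }
}

#' Call ROH islands from the incidence track
#'
#' Markers strictly above the [island_threshold()] are merged into islands:
#' maximal runs of consecutive qualifying markers, split where two adjacent
#' qualifying markers are separated by more than `max_gap_kb` (the same gap
#' rule as ROH calling). Island bounds are the first and last qualifying
#' marker positions.
#'
#' @inheritParams island_threshold
#' @param max_gap_kb gap splitting rule (default 1500).
#' @return A tibble of class `roh_islands`: `chromosome`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`, `peak_proportion`. Zero rows (with a
#'   warning) when the incidence is constant.
#' @export
call_islands <- function(track, quantile = 0.999, max_gap_kb = 1500,
                         method = c("zscore", "empirical")) {
  method <- match.arg(method)
  empty <- tibble::tibble(
    chromosome = character(), start_bp = integer(), end_bp = integer(),
    n_snps = integer(), length_bp = integer(), peak_proportion = numeric()
  )
  thr <- island_threshold(track, quantile, method)
  if (!is.finite(thr)) {
    class(empty) <- c("roh_islands", class(empty))
    return(empty)
  }
  qual <- track$n_roh > thr
  if (!any(qual)) {
    class(empty) <- c("roh_islands", class(empty))
    return(empty)
  }
  out <- list()
  for (chr in unique(track$chromosome)) {
    rows <- which(track$chromosome == chr)
    q <- qual[rows]
    if (!any(q)) next
    pos <- track$position_bp[rows]
    gap_break <- c(FALSE, diff(pos) > max_gap_kb * 1000)
    run_id <- cumsum(!q | gap_break)
    idx <- which(q)
    for (r in split(idx, run_id[idx])) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chromosome = chr,
        start_bp = pos[r[1]],
        end_bp = pos[r[length(r)]],
        n_snps = length(r),
        length_bp = pos[r[length(r)]] - pos[r[1]],
        peak_proportion = max(track$proportion[rows][r])
      )
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "count_threshold") <- thr
  class(res) <- c("roh_islands", class(tibble::tibble()))
  res
}
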