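#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on one marker's genotype counts: conditional on the
#' observed allele counts, the probability of every possible heterozygote
#' count (same parity as the observed one) is evaluated, and the p-value is
#' the sum of probabilities of configurations no more probable than the
#' observed configuration. This is the standard exact formulation (not
#' mid-p, not chi-square), as used by PLINK's `--hwe` filter.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (A1/A1 homozygote,
#'   heterozygote, A2/A2 homozygote). Vectorized.
#' @return Exact p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(3, 5, 2)
#' hwe_exact_test(10, 0, 0) # monomorphic: p = 1
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  if (length(n_het) > 1L || length(n_hom1) > 1L || length(n_hom2) > 1L) {
    return(mapply(hwe_exact_test, n_hom1, n_het, n_hom2))
  }
  for (v in list(n_hom1, n_het, n_hom2)) {
    if (is.na(v) || v < 0 || v != floor(v)) abort("counts must be non-negative integers")
  }
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) abort("all genotype counts are zero: HWE test undefined")

  n_a <- 2 * n_hom1 + n_het      # copies of allele 1
  n_b <- 2 * n - n_a
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)       # monomorphic: a single configuration

  hets <- seq.int(rare %% 2, rare, by = 2)
  # log P(het = h | allele counts): multinomial over genotype configurations
  logp <- lfactorial(n) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial((n + (rare - hets) / 2) - rare) +  # other-homozygote count
    hets * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Quality-control parameter set
#'
#' @param min_call_rate keep markers with call rate at or above this
#'   fraction (default 0.9).
#' @param min_hwe_p keep markers with exact Hardy-Weinberg p strictly above
#'   this value (default `1e-6`).
#' @param min_maf optional: keep markers with minor allele frequency at or
#'   above this fraction. `NULL` (default) disables the filter — ROH
#'   detection runs without a MAF filter; the SNP-by-SNP inbreeding
#'   estimators conventionally use 0.05.
#' @param autosomes_only drop markers on sex or unassigned chromosomes
#'   (default `TRUE`).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_call_rate = 0.9, min_hwe_p = 1e-6, min_maf = NULL,
                      autosomes_only = TRUE) {
  for (v in c(min_call_rate, min_hwe_p, min_maf)) {
    if (!is.null(v) && (v < 0 || v > 1)) abort("QC thresholds must be in [0, 1]")
  }
  structure(
    list(min_call_rate = min_call_rate, min_hwe_p = min_hwe_p,
         min_maf = min_maf, autosomes_only = isTRUE(autosomes_only)),
    class = "qc_params"
  )
}

#' Per-marker call rate, minor allele frequency and HWE p-value
#'
#' Annotates the marker table with `call_rate`, `maf` (frequency of the less
#' common allele, from non-missing calls only) and `hwe_p` (exact test).
#' Markers with no non-missing calls get `maf = NA` and `hwe_p = NA`.
#'
#' @param gm a [genotypes()] object.
#' @return The `genotypes` object with annotated markers.
#' @export
compute_marker_stats <- function(gm) {
  if (n_markers(gm) == 0L) abort("empty genotype matrix")
  calls <- gm$calls
  n <- n_samples(gm)
  nonmiss <- colSums(!is.na(calls))
  n_hom1 <- colSums(calls == 2L, na.rm = TRUE)
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  n_hom2 <- colSums(calls == 0L, na.rm = TRUE)

  p1 <- ifelse(nonmiss > 0, (2 * n_hom1 + n_het) / (2 * nonmiss), NA_real_)
  gm$markers$call_rate <- unname(nonmiss / n)
  gm$markers$maf <- unname(pmin(p1, 1 - p1))
  gm$markers$hwe_p <- unname(ifelse(
    nonmiss > 0,
    mapply(function(a, h, b) if (a + h + b == 0) NA_real_ else hwe_exact_test(a, h, b),
           n_hom1, n_het, n_hom2),
    NA_real_
  ))
  gm
}

#' Apply marker quality control
#'
#' Filters markers in a fixed order — non-autosomal chromosomes, call rate,
#' Hardy-Weinberg, minor allele frequency — so removal counts are
#' reproducible. Marker statistics are computed first if absent. Markers
#' with entirely missing calls fail the call-rate filter.
#'
#' @param gm a [genotypes()] object.
#' @param params a [qc_params()] list.
#' @return A list with elements `genotypes` (the filtered object) and
#'   `report` (a tibble of removal counts per criterion, in filter order).
#' @export
apply_qc <- function(gm, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (!all(c("call_rate", "maf", "hwe_p") %in% names(gm$markers))) {
    gm <- compute_marker_stats(gm)
  }
  n0 <- n_markers(gm)
  report <- tibble::tibble(
    criterion = c("non_autosome", "call_rate", "hwe", "maf"),
    threshold = c(NA_real_, params$min_call_rate, params$min_hwe_p,
                  params$min_maf %||% NA_real_),
    n_removed = 0L
  )

  keep_step <- function(gm, keep) gm[, which(keep)]

  if (params$autosomes_only) {
    keep <- is_autosome(gm$markers$chromosome)
    report$n_removed[1] <- sum(!keep)
    gm <- keep_step(gm, keep)
  }
  keep <- !is.na(gm$markers$call_rate) & gm$markers$call_rate >= params$min_call_rate
  report$n_removed[2] <- sum(!keep)
  gm <- keep_step(gm, keep)

  keep <- is.na(gm$markers$hwe_p) | gm$markers$hwe_p > params$min_hwe_p
  report$n_removed[3] <- sum(!keep)
  gm <- keep_step(gm, keep)

  if (!is.null(params$min_maf)) {
    keep <- !is.na(gm$markers$maf) & gm$markers$maf >= params$min_maf
    report$n_removed[4] <- sum(!keep)
    gm <- keep_step(gm, keep)
  }

  if (n_markers(gm) == 0L && n0 > 0L) {
    warn("all markers removed by quality control")
  }
  list(genotypes = gm, report = report)
}
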