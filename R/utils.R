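#' @importFrom rlang %||% abort warn
#' @importFrom stats rbinom rpois runif sd cor qnorm quantile phyper p.adjust
#' @importFrom utils head tail
NULL

# Chromosome labels: autosomes are positive integers; anything else
# (Z, W, MT, 0, un*) is flagged non-autosomal.
is_autosome <- function(chrom) {
  suppressWarnings(n <- as.numeric(as.character(chrom)))
  !is.na(n) & n == floor(n) & n > 0
}

# Sort order that puts numeric chromosome labels first, in numeric order,
# then the rest alphabetically.
chrom_order <- function(chrom) {
  chrom <- as.character(chrom)
  n <- suppressWarnings(as.numeric(chrom))
  order(is.na(n), n, chrom)
}

# Strip common chromosome-name prefixes (chr, Chr., GGA) so islands,
# gene annotation and QTL records can share a naming scheme.
normalize_chrom <- function(chrom) {
  sub("^(chr\\.?|gga)[ _]?", "", as.character(chrom), ignore.case = TRUE)
}

# round-half-up to the nearest integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single non-negative integer", name))
  }
}
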