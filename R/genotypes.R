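#' Construct a genotype matrix object
#'
#' The substrate of every analysis in rohkit: biallelic SNP-array calls for a
#' set of individuals, together with the marker map and sample metadata.
#' Calls count copies of allele A1 (the BIM column-5 allele, usually the
#' minor allele), so `2` is homozygous A1/A1, `1` heterozygous, `0`
#' homozygous A2/A2 and `NA` missing — the PLINK 1 binary convention.
#'
#' @param calls integer matrix, samples in rows and markers in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param markers data frame with one row per marker: `chromosome`,
#'   `marker_id`, `position_bp` (1-based), `allele_a1`, `allele_a2`.
#' @param samples data frame with one row per individual: `individual_id`
#'   plus optional metadata such as `generation`, `sex`, `family_id`.
#'
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  markers <- tibble::as_tibble(markers)
  samples <- tibble::as_tibble(samples)

  if (!all(c("chromosome", "marker_id", "position_bp") %in% names(markers))) {
    abort("`markers` needs columns chromosome, marker_id, position_bp")
  }
  if (!"allele_a1" %in% names(markers)) markers$allele_a1 <- "A"
  if (!"allele_a2" %in% names(markers)) markers$allele_a2 <- "B"
  if (!"individual_id" %in% names(samples)) {
    abort("`samples` needs column individual_id")
  }
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers)) {
    abort(sprintf(
      "calls is %d x %d but there are %d samples and %d markers",
      nrow(calls), ncol(calls), nrow(samples), nrow(markers)
    ))
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("non-missing calls must be 0, 1 or 2 (copies of allele A1)")
  }
  if (anyDuplicated(samples$individual_id)) {
    abort("individual_id must be unique within a dataset")
  }
  markers$chromosome <- as.character(markers$chromosome)
  rownames(calls) <- samples$individual_id
  colnames(calls) <- markers$marker_id

  structure(
    list(calls = calls, markers = markers, samples = samples),
    class = "genotypes"
  )
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf(
    "<genotypes> %d individuals x %d markers on %d chromosome(s)\n",
    n_samples(x), n_markers(x), length(unique(x$markers$chromosome))
  ))
  stat_cols <- intersect(c("call_rate", "maf", "hwe_p"), names(x$markers))
  if (length(stat_cols)) {
    cat("  marker stats:", paste(stat_cols, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of individuals / markers in a genotypes object
#' @param gm a [genotypes()] object.
#' @return An integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_markers <- function(gm) ncol(gm$calls)

#' @export
dim.genotypes <- function(x) dim(x$calls)

#' Subset a genotypes object
#'
#' `gm[i, j]` keeps individuals `i` and markers `j` (any usual matrix index).
#' Marker statistics columns, if present, are carried along unchanged; they
#' refer to the sample they were computed from.
#'
#' @param x a [genotypes()] object.
#' @param i,j sample and marker indices.
#' @param ... unused.
#' @return A `genotypes` object.
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_markers(x))
  genotypes(
    x$calls[i, j, drop = FALSE],
    x$markers[j, , drop = FALSE],
    x$samples[i, , drop = FALSE]
  )
}

#' Sort markers into canonical genome order
#'
#' Orders markers by chromosome (numeric labels first, numerically) and
#' position. Positions must be strictly increasing within a chromosome after
#' sorting; ties indicate duplicate map entries and raise an error.
#'
#' @param gm a [genotypes()] object.
#' @return The reordered `genotypes` object.
#' @export
sort_markers <- function(gm) {
  chr <- gm$markers$chromosome
  chr_levels <- unique(chr)[chrom_order(unique(chr))]
  ord <- order(match(chr, chr_levels), gm$markers$position_bp)
  out <- gm[, ord]
  dup <- dplyr::group_by(out$markers, .data$chromosome)
  dup <- dplyr::summarise(dup, dup = anyDuplicated(.data$position_bp) > 0L)
  if (any(dup$dup)) {
    abort("duplicate marker positions within a chromosome after sorting")
  }
  out
}

markers_sorted <- function(gm) {
  m <- gm$markers
  all(unlist(tapply(m$position_bp, factor(m$chromosome, levels = unique(m$chromosome)),
                    function(p) all(diff(p) > 0), simplify = FALSE)))
}
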