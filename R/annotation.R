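#' Read genomic features from GFF3
#'
#' A tolerant reader: header/comment lines are skipped, rows that do not
#' have nine tab-separated columns are dropped with a single warning giving
#' their count (annotation dumps are often ragged). Coordinates stay
#' 1-based inclusive, as in GFF3. Attribute values are extracted from
#' `key=value;...` pairs.
#'
#' @param path GFF3 file path.
#' @param feature_filter optional character vector of column-3 feature
#'   types to keep (e.g. `"gene"`).
#' @param normalize_chromosomes strip `chr`/`Chr.`/`GGA` prefixes from
#'   sequence names (default `TRUE`) so genes, QTLs and islands share a
#'   naming scheme.
#' @return A tibble: `chromosome`, `start_bp`, `end_bp`, `feature_type`,
#'   `feature_id`, `name`, `attributes` (the raw column-9 string).
#' @export
read_gff3 <- function(path, feature_filter = NULL,
                      normalize_chromosomes = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) != 9L
  if (any(bad)) {
    warn(sprintf("skipped %d malformed GFF row(s)", sum(bad)))
    fields <- fields[!bad]
  }
  if (!length(fields)) {
    return(tibble::tibble(
      chromosome = character(), start_bp = integer(), end_bp = integer(),
      feature_type = character(), feature_id = character(),
      name = character(), attributes = character()
    ))
  }
  m <- do.call(rbind, fields)
  start_bp <- suppressWarnings(as.integer(m[, 4]))
  end_bp <- suppressWarnings(as.integer(m[, 5]))
  keep <- !is.na(start_bp) & !is.na(end_bp) & start_bp <= end_bp
  if (any(!keep)) {
    warn(sprintf("skipped %d GFF row(s) with bad coordinates", sum(!keep)))
  }
  out <- tibble::tibble(
    chromosome = m[keep, 1],
    start_bp = start_bp[keep],
    end_bp = end_bp[keep],
    feature_type = m[keep, 3],
    feature_id = gff_attr(m[keep, 9], c("ID", "gene_id", "QTL_ID")),
    name = gff_attr(m[keep, 9], c("Name", "gene", "trait")),
    attributes = m[keep, 9]
  )
  if (normalize_chromosomes) out$chromosome <- normalize_chrom(out$chromosome)
  if (!is.null(feature_filter)) {
    out <- out[out$feature_type %in% feature_filter, , drop = FALSE]
  }
  out
}

# first non-missing attribute among `keys`, per row
gff_attr <- function(attr_strings, keys) {
  vapply(attr_strings, function(s) {
    kv <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- sub("^\\s+", "", kv)
    for (key in keys) {
      hit <- kv[startsWith(kv, paste0(key, "="))]
      if (length(hit)) {
        v <- sub("^[^=]+=", "", hit[1])
        return(gsub('^"|"$', "", v))
      }
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read QTL records in the Animal-QTLdb GFF dialect
#'
#' Wraps [read_gff3()]: QTL identity comes from the `QTL_ID` attribute,
#' the trait name from `Name`/`trait`, and the trait class from the
#' `trait_type` attribute when present, falling back to the GFF type
#' column (where QTLdb dumps store the class). Records without a
#' recognisable class are grouped as `"other"`.
#'
#' @inheritParams read_gff3
#' @return A tibble as [read_gff3()] plus `trait_class`.
#' @export
read_qtl_gff <- function(path, normalize_chromosomes = TRUE) {
  out <- read_gff3(path, normalize_chromosomes = normalize_chromosomes)
  cls <- gff_attr(out$attributes, c("trait_type", "Trait_type", "trait_class"))
  cls <- ifelse(is.na(cls), out$feature_type, cls)
  cls[is.na(cls) | cls == "" | cls == "."] <- "other"
  out$trait_class <- cls
  out
}

#' Features overlapping ROH islands
#'
#' Reports every feature whose interval intersects an island interval by at
#' least 1 bp (closed, 1-based intervals on both sides). Chromosome names
#' present in only one of the inputs trigger a warning with the unmatched
#' counts.
#'
#' @param islands a [call_islands()] tibble.
#' @param features a [read_gff3()] / [read_qtl_gff()] tibble.
#' @return A tibble: island columns (`island`, `chromosome`, `island_start`,
#'   `island_end`) joined with the overlapping feature rows.
#' @export
overlap_features <- function(islands, features) {
  only_isl <- setdiff(islands$chromosome, features$chromosome)
  only_feat <- setdiff(features$chromosome, islands$chromosome)
  if (length(only_isl) || length(only_feat)) {
    warn(sprintf(
      "chromosome names unmatched across inputs: %d island-only, %d feature-only",
      length(only_isl), length(only_feat)
    ))
  }
  if (!nrow(islands) || !nrow(features)) {
    return(tibble::tibble(
      island = integer(), chromosome = character(),
      island_start = integer(), island_end = integer(),
      feature_id = character(), name = character(),
      feature_type = character(), start_bp = integer(), end_bp = integer()
    ))
  }
  gr_isl <- GenomicRanges::GRanges(
    islands$chromosome,
    IRanges::IRanges(islands$start_bp, islands$end_bp)
  )
  gr_feat <- GenomicRanges::GRanges(
    features$chromosome,
    IRanges::IRanges(features$start_bp, features$end_bp)
  )
  # seqlevel mismatches are already reported above with counts
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_isl, gr_feat))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- dplyr::bind_cols(
    tibble::tibble(
      island = qi,
      chromosome = islands$chromosome[qi],
      island_start = islands$start_bp[qi],
      island_end = islands$end_bp[qi]
    ),
    features[si, setdiff(names(features), c("chromosome", "attributes")),
             drop = FALSE]
  )
  out
}

#' QTL trait-class enrichment in ROH islands
#'
#' For every trait class in the database: a hypergeometric upper-tail test
#' of whether the island-overlapping QTLs are enriched for the class, with
#' population size `N_db` (all database QTLs), `K_db` successes (database
#' QTLs of the class), `n` draws (distinct overlapping QTLs) and `k`
#' observed (overlapping QTLs of the class); Benjamini-Hochberg adjustment
#' across classes. QTLs are counted as distinct `feature_id`s.
#'
#' @param overlapped tibble of QTLs overlapping islands (from
#'   [overlap_features()] on a [read_qtl_gff()] table), with `feature_id`
#'   and `trait_class`.
#' @param database the full QTL database tibble (`feature_id`,
#'   `trait_class`).
#' @return A tibble sorted by adjusted p-value: `trait_class`, `k_overlap`,
#'   `n_overlap_total`, `K_db`, `N_db`, `p`, `p_adj`.
#' @export
qtl_enrichment <- function(overlapped, database) {
  if (!nrow(database)) abort("empty QTL database")
  db <- dplyr::distinct(tibble::as_tibble(database)[, c("feature_id", "trait_class")])
  ov <- dplyr::distinct(tibble::as_tibble(overlapped)[, c("feature_id", "trait_class")])
  missing_cls <- setdiff(ov$trait_class, db$trait_class)
  if (length(missing_cls)) {
    abort(sprintf("trait class in overlap but absent from database: %s",
                  paste(missing_cls, collapse = ", ")))
  }
  n_total <- nrow(ov)
  n_db <- nrow(db)
  classes <- sort(unique(db$trait_class))
  k <- vapply(classes, function(cl) sum(ov$trait_class == cl), integer(1),
              USE.NAMES = FALSE)
  bigk <- vapply(classes, function(cl) sum(db$trait_class == cl), integer(1),
                 USE.NAMES = FALSE)
  p <- phyper(k - 1, bigk, n_db - bigk, n_total, lower.tail = FALSE)
  out <- tibble::tibble(
    trait_class = classes,
    k_overlap = k,
    n_overlap_total = n_total,
    K_db = bigk,
    N_db = n_db,
    p = p,
    p_adj = p.adjust(p, method = "BH")
  )
  dplyr::arrange(out, .data$p_adj, .data$p)
}
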