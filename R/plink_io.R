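#' Read PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Decodes the SNP-major PLINK 1 binary layout (magic bytes `6c 1b 01`,
#' two bits per call). Marker and sample order are preserved from the BIM
#' and FAM files; calls count copies of the BIM column-5 allele (A1).
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` are
#'   read. Alternatively give the three paths explicitly.
#' @param bed_path,bim_path,fam_path explicit file paths (override `prefix`).
#' @return A [genotypes()] object.
#' @export
read_plink_binary <- function(prefix = NULL, bed_path = NULL, bim_path = NULL,
                              fam_path = NULL) {
  if (!is.null(prefix)) {
    bed_path <- bed_path %||% paste0(prefix, ".bed")
    bim_path <- bim_path %||% paste0(prefix, ".bim")
    fam_path <- fam_path %||% paste0(prefix, ".fam")
  }
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }

  bim <- readr::read_table(
    bim_path,
    col_names = c("chromosome", "marker_id", "cm", "position_bp",
                  "allele_a1", "allele_a2"),
    col_types = "ccdicc", progress = FALSE
  )
  fam <- readr::read_table(
    fam_path,
    col_names = c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype"),
    col_types = "cccccc", progress = FALSE
  )
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L ||
      raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK 1 BED file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) {
    abort("only SNP-major BED files are supported (third byte must be 0x01)")
  }
  bytes_per_marker <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_marker * m) {
    abort(sprintf(
      "BED payload is %d bytes but BIM x FAM implies %d (integrity error)",
      length(payload), bytes_per_marker * m
    ))
  }

  b <- as.integer(payload)
  # unpack the four 2-bit fields of every byte; sample s of marker j sits in
  # bits 2*((s-1) %% 4) of byte (s-1) %/% 4 of that marker's block
  pairs <- matrix(0L, nrow = 4L * bytes_per_marker, ncol = m)
  for (k in 0:3) {
    pairs[seq.int(k + 1L, by = 4L, length.out = bytes_per_marker), ] <-
      bitwAnd(bitwShiftR(b, 2L * k), 3L)
  }
  pairs <- pairs[seq_len(n), , drop = FALSE]
  # PLINK 2-bit codes: 00 hom A1, 01 missing, 10 het, 11 hom A2
  calls <- matrix(c(2L, NA_integer_, 1L, 0L)[pairs + 1L], nrow = n, ncol = m)

  genotypes(calls, bim[, c("chromosome", "marker_id", "position_bp",
                           "allele_a1", "allele_a2")], fam_to_samples(fam))
}

fam_to_samples <- function(fam) {
  out <- tibble::tibble(
    individual_id = fam$individual_id,
    family_id = fam$family_id,
    sex = fam$sex
  )
  out
}

#' Read PLINK text genotypes (PED/MAP)
#'
#' Whitespace-delimited PED/MAP. Allele code `"0"` is missing; a genotype
#' with either allele missing is treated as a missing call. Per-marker A1 is
#' taken as the minor allele (ties broken alphabetically), matching PLINK's
#' behaviour when importing text genotypes.
#'
#' @param ped_path,map_path file paths.
#' @return A [genotypes()] object.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- readr::read_table(
    map_path,
    col_names = c("chromosome", "marker_id", "cm", "position_bp"),
    col_types = "ccdi", progress = FALSE
  )
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  if (length(unique(len)) != 1L || len[1] != 6L + 2L * m) {
    abort(sprintf(
      "ragged or mis-sized PED rows: expected %d fields, found %s",
      6L + 2L * m, paste(unique(len), collapse = "/")
    ))
  }
  ped <- do.call(rbind, fields)
  n <- nrow(ped)

  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    warn(sprintf("%d half-missing genotypes treated as missing", sum(half)))
  }
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_

  allele_a1 <- character(m)
  allele_a2 <- character(m)
  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    tab <- sort(table(al[!is.na(al)]))
    alleles <- names(tab)
    if (length(alleles) > 2L) {
      abort(sprintf("marker %s has >2 alleles", map$marker_id[j]))
    }
    if (length(alleles) == 0L) {
      allele_a1[j] <- "0"; allele_a2[j] <- "0"
      next
    }
    if (length(alleles) == 1L) {
      allele_a1[j] <- alleles[1]; allele_a2[j] <- "0"
    } else {
      # minor allele first; alphabetical on ties
      if (tab[[1]] == tab[[2]]) alleles <- sort(alleles)
      allele_a1[j] <- alleles[1]; allele_a2[j] <- alleles[2]
    }
    calls[, j] <- (a1[, j] == allele_a1[j]) + (a2[, j] == allele_a1[j])
  }

  markers <- tibble::tibble(
    chromosome = map$chromosome, marker_id = map$marker_id,
    position_bp = map$position_bp, allele_a1 = allele_a1, allele_a2 = allele_a2
  )
  samples <- tibble::tibble(
    individual_id = ped[, 2], family_id = ped[, 1], sex = ped[, 5]
  )
  genotypes(calls, markers, samples)
}

#' Write genotypes to PLINK files
#'
#' @param gm a [genotypes()] object.
#' @param prefix output path prefix.
#' @param format `"bed"` for BED/BIM/FAM, `"ped"` for PED/MAP.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  if (format == "bed") write_plink_binary(gm, prefix) else write_plink_text(gm, prefix)
  invisible(prefix)
}

write_plink_binary <- function(gm, prefix) {
  n <- n_samples(gm)
  m <- n_markers(gm)
  fam <- data.frame(
    fid = sample_col(gm$samples, "family_id", gm$samples$individual_id),
    iid = gm$samples$individual_id,
    pat = "0", mat = "0",
    sex = sample_col(gm$samples, "sex", "0"),
    phe = "-9"
  )
  fam$fid[is.na(fam$fid)] <- fam$iid[is.na(fam$fid)]
  fam$sex[is.na(fam$sex)] <- "0"
  readr::write_delim(fam, paste0(prefix, ".fam"), delim = " ", col_names = FALSE)
  bim <- data.frame(
    chr = gm$markers$chromosome, id = gm$markers$marker_id, cm = 0,
    pos = gm$markers$position_bp,
    a1 = gm$markers$allele_a1, a2 = gm$markers$allele_a2
  )
  readr::write_delim(bim, paste0(prefix, ".bim"), delim = "\t", col_names = FALSE)

  # 2-bit codes: call 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- gm$calls
  pairs <- matrix(1L, n, m)
  pairs[!is.na(code) & code == 2L] <- 0L
  pairs[!is.na(code) & code == 1L] <- 2L
  pairs[!is.na(code) & code == 0L] <- 3L
  pad <- (4L - n %% 4L) %% 4L
  if (pad > 0L) pairs <- rbind(pairs, matrix(0L, pad, m))
  np <- nrow(pairs)
  idx <- seq.int(1L, np, by = 4L)
  bytes <- pairs[idx, , drop = FALSE] +
    4L * pairs[idx + 1L, , drop = FALSE] +
    16L * pairs[idx + 2L, , drop = FALSE] +
    64L * pairs[idx + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
}

write_plink_text <- function(gm, prefix) {
  n <- n_samples(gm)
  m <- n_markers(gm)
  a1 <- gm$markers$allele_a1
  a2 <- gm$markers$allele_a2
  first <- matrix(a2, n, m, byrow = TRUE)
  second <- matrix(a2, n, m, byrow = TRUE)
  a1m <- matrix(a1, n, m, byrow = TRUE)
  het <- !is.na(gm$calls) & gm$calls == 1L
  hom1 <- !is.na(gm$calls) & gm$calls == 2L
  first[het | hom1] <- a1m[het | hom1]
  second[hom1] <- a1m[hom1]
  first[is.na(gm$calls)] <- "0"
  second[is.na(gm$calls)] <- "0"

  geno <- matrix("", n, 2L * m)
  geno[, 2L * seq_len(m) - 1L] <- first
  geno[, 2L * seq_len(m)] <- second
  fid <- sample_col(gm$samples, "family_id", gm$samples$individual_id)
  fid[is.na(fid)] <- gm$samples$individual_id[is.na(fid)]
  sex <- sample_col(gm$samples, "sex", rep("0", n))
  sex[is.na(sex)] <- "0"
  ped <- cbind(fid, gm$samples$individual_id, "0", "0", sex, "-9", geno)
  writeLines(apply(ped, 1, paste, collapse = " "), paste0(prefix, ".ped"))

  map <- data.frame(
    chr = gm$markers$chromosome, id = gm$markers$marker_id, cm = 0,
    pos = gm$markers$position_bp
  )
  readr::write_delim(map, paste0(prefix, ".map"), delim = "\t", col_names = FALSE)
}

sample_col <- function(samples, col, default) {
  if (col %in% names(samples)) samples[[col]] else rep_len(default, nrow(samples))
}
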