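#' Recombination map for simulated genotypes
#'
#' Chromosome lengths, evenly spaced marker positions at a chip-like
#' density, and map lengths in Morgans under a uniform cM/Mb rate.
#'
#' @param chrom_lengths_mb numeric vector of chromosome physical lengths in
#'   Mb; names become chromosome labels (default `1, 2, ...`).
#' @param snps_per_mb marker density (default 57, approximating a 60K chip
#'   on a 0.94 Gb genome).
#' @param cm_per_mb recombination rate, uniform along each chromosome
#'   (default 1 cM/Mb). May be a vector, one value per chromosome.
#' @return A list of class `recomb_map` with elements `chrom` (tibble:
#'   `chromosome`, `length_bp`, `morgans`) and `markers` (tibble:
#'   `chromosome`, `marker_id`, `position_bp`).
#' @export
recomb_map <- function(chrom_lengths_mb, snps_per_mb = 57, cm_per_mb = 1) {
  if (any(chrom_lengths_mb <= 0)) abort("chromosome lengths must be positive")
  labels <- names(chrom_lengths_mb) %||% as.character(seq_along(chrom_lengths_mb))
  cm_per_mb <- rep_len(cm_per_mb, length(chrom_lengths_mb))
  chrom <- tibble::tibble(
    chromosome = labels,
    length_bp = round(chrom_lengths_mb * 1e6),
    morgans = chrom_lengths_mb * cm_per_mb / 100
  )
  markers <- purrr::pmap_dfr(chrom, function(chromosome, length_bp, morgans) {
    k <- max(2L, round(length_bp / 1e6 * snps_per_mb))
    spacing <- length_bp / k
    tibble::tibble(
      chromosome = chromosome,
      marker_id = sprintf("snp_%s_%d", chromosome, seq_len(k)),
      position_bp = as.integer(round(spacing * (seq_len(k) - 0.5)))
    )
  })
  structure(list(chrom = chrom, markers = markers), class = "recomb_map")
}

#' Chicken-like autosomal map
#'
#' Twenty-eight autosomes with lengths proportional to the chicken
#' (GRCg6a-like) karyotype — a few large macrochromosomes and many
#' microchromosomes — rescaled so the genome totals 0.94 Gb, the autosomal
#' length used for `F_ROH`. `scale` shrinks every chromosome for quick
#' tests while preserving marker density.
#'
#' @param scale multiplicative factor on chromosome lengths (default 1).
#' @param snps_per_mb,cm_per_mb passed to [recomb_map()].
#' @return A `recomb_map`.
#' @export
study_map <- function(scale = 1, snps_per_mb = 57, cm_per_mb = 1) {
  mb <- c(197, 149, 111, 91, 60, 36, 36, 30, 24, 21, 20, 20, 18, 15, 13, 11,
          11, 11, 10, 14, 7, 4, 6, 6, 3, 5, 5, 4)
  mb <- mb / sum(mb) * 940 * scale
  names(mb) <- as.character(seq_along(mb))
  recomb_map(mb, snps_per_mb = snps_per_mb, cm_per_mb = cm_per_mb)
}

#' Simulate founder haplotypes
#'
#' Draws `2 * n_founders` haplotypes: each marker's A1-allele frequency is
#' drawn once from `maf_law`, then haplotype alleles are independent
#' Bernoulli draws (founders are unrelated and in linkage equilibrium).
#' Every haplotype carries a unique ancestry label, the unit of
#' identity-by-descent tracking in [gene_drop()].
#'
#' @param n_founders number of founder individuals (at least 2).
#' @param map a [recomb_map()].
#' @param maf_law either a function `f(m)` returning `m` allele frequencies
#'   in `(0, 0.5]`, or a single number for a point mass. Default: uniform
#'   on `[0.05, 0.5]`, a typical post-QC chip spectrum.
#' @param seed integer seed (optional; sets the session RNG).
#' @return A list of class `founder_pool`: `alleles` (2n x m 0/1 matrix,
#'   rows are haplotype labels), `freq`, `map`, `n_founders`.
#' @export
simulate_founders <- function(n_founders, map,
                              maf_law = function(m) runif(m, 0.05, 0.5),
                              seed = NULL) {
  if (n_founders < 2) abort("need at least 2 founders")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map$markers)
  p <- if (is.function(maf_law)) maf_law(m) else rep_len(maf_law, m)
  if (any(p <= 0) || any(p > 0.5)) {
    abort("maf_law must yield frequencies in (0, 0.5]")
  }
  nh <- 2L * n_founders
  alleles <- matrix(
    rbinom(nh * m, 1L, rep(p, each = nh)),
    nrow = nh, ncol = m
  )
  structure(
    list(alleles = alleles, freq = p, map = map, n_founders = n_founders),
    class = "founder_pool"
  )
}

# --- haplotype mosaic machinery ------------------------------------------
# A haplotype on one chromosome is a label mosaic: `ends` are cumulative
# breakpoint positions (last = chromosome length), `labs` the founder
# haplotype label of each piece.

hap_segment <- function(lab, length_bp) list(ends = length_bp, labs = lab)

# piece of `hap` covering (lo, hi], in absolute coordinates
hap_extract <- function(hap, lo, hi) {
  first <- sum(hap$ends <= lo) + 1L
  last <- sum(hap$ends < hi) + 1L
  ends <- hap$ends[first:last]
  ends[length(ends)] <- hi
  list(ends = ends, labs = hap$labs[first:last])
}

hap_merge_runs <- function(hap) {
  if (length(hap$labs) <= 1L) return(hap)
  keep <- c(hap$labs[-1] != hap$labs[-length(hap$labs)], TRUE)
  list(ends = hap$ends[keep], labs = hap$labs[keep])
}

# one meiosis on one chromosome: Haldane model, crossover count Poisson
# with mean = map length in Morgans, positions uniform, no interference
meiosis_chrom <- function(hapA, hapB, length_bp, morgans) {
  k <- rpois(1L, morgans)
  start_first <- runif(1) < 0.5
  if (k == 0L) return(if (start_first) hapA else hapB)
  cuts <- sort(runif(k, 0, length_bp))
  bounds <- c(0, cuts, length_bp)
  pieces <- vector("list", length(bounds) - 1L)
  for (i in seq_along(pieces)) {
    src <- if (xor(i %% 2L == 1L, !start_first)) hapA else hapB
    pieces[[i]] <- hap_extract(src, bounds[i], bounds[i + 1L])
  }
  hap_merge_runs(list(
    ends = unlist(lapply(pieces, `[[`, "ends")),
    labs = unlist(lapply(pieces, `[[`, "labs"))
  ))
}

# label at each of `pos` (sorted or not) for one chromosome haplotype
hap_labels_at <- function(hap, pos) {
  hap$labs[findInterval(pos, c(0, hap$ends), left.open = TRUE)]
}

# intervals of one chromosome where the two haplotypes carry the same label
autozygous_intervals <- function(h1, h2) {
  ends <- sort(unique(c(h1$ends, h2$ends)))
  mids <- (c(0, head(ends, -1)) + ends) / 2
  same <- hap_labels_at(h1, mids) == hap_labels_at(h2, mids)
  if (!any(same)) return(NULL)
  r <- rle(same)
  hi_idx <- cumsum(r$lengths)
  lo_idx <- hi_idx - r$lengths + 1L
  starts <- c(0, ends)[lo_idx][r$values]
  stops <- ends[hi_idx][r$values]
  cbind(start = starts, end = stops)
}

#' Drop genes down a pedigree with recombination
#'
#' Simulates Mendelian transmission of labelled founder haplotypes through
#' a pedigree (Haldane crossover model), emits SNP genotypes at the map's
#' marker positions, and records the exact truth: per-individual autozygous
#' segments (where both haplotypes carry the same founder-haplotype label),
#' the pedigree-expected inbreeding coefficient, and the realized autozygous
#' fraction of the genome.
#'
#' @param ped a [pedigree()]; founders are taken from the pool in order.
#' @param founders a [simulate_founders()] pool with at least as many
#'   founders as the pedigree has.
#' @param seed optional integer seed.
#' @param error_rate per-call probability that a genotype is replaced by one
#'   of the other two codes (default 0).
#' @param missing_rate per-call probability of a missing genotype (default 0).
#' @param plant optional tibble (`chromosome`, `start_bp`, `end_bp`): force
#'   these intervals to be autozygous for one shared founder haplotype in
#'   the individuals selected by `plant_individuals` — used to embed known
#'   autozygous segments or a population-shared sweep.
#' @param plant_individuals character vector of individual ids, or a single
#'   fraction in (0, 1] of individuals sampled at random.
#' @return A list: `genotypes` (a [genotypes()] object with `generation` in
#'   the sample table) and `truth` (list with `segments`, `individuals`
#'   (`expected_f`, `realized_f`), `pedigree`, `map`).
#' @export
gene_drop <- function(ped, founders, seed = NULL, error_rate = 0,
                      missing_rate = 0, plant = NULL, plant_individuals = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(founders, "founder_pool"))
  if (!is.null(seed)) set.seed(seed)
  map <- founders$map
  chroms <- map$chrom
  n_chr <- nrow(chroms)
  n <- nrow(ped)

  founder_rows <- which(is.na(ped$sire_id))
  if (length(founder_rows) > founders$n_founders) {
    abort("founder pool smaller than the pedigree's founder count")
  }
  sire <- match(ped$sire_id, ped$individual_id)
  dam <- match(ped$dam_id, ped$individual_id)
  if (any(is.na(sire) & !is.na(ped$sire_id))) abort("unknown parent reference")

  # haps[[i]] is a list of n_chr chromosomes, each list(h1, h2)
  haps <- vector("list", n)
  f_i <- 0L
  for (i in seq_len(n)) {
    if (is.na(sire[i])) {
      f_i <- f_i + 1L
      haps[[i]] <- lapply(seq_len(n_chr), function(c) list(
        h1 = hap_segment(2L * f_i - 1L, chroms$length_bp[c]),
        h2 = hap_segment(2L * f_i, chroms$length_bp[c])
      ))
    } else {
      hs <- haps[[sire[i]]]
      hd <- haps[[dam[i]]]
      haps[[i]] <- lapply(seq_len(n_chr), function(c) list(
        h1 = meiosis_chrom(hs[[c]]$h1, hs[[c]]$h2,
                           chroms$length_bp[c], chroms$morgans[c]),
        h2 = meiosis_chrom(hd[[c]]$h1, hd[[c]]$h2,
                           chroms$length_bp[c], chroms$morgans[c])
      ))
    }
  }

  if (!is.null(plant)) {
    ids <- if (is.numeric(plant_individuals)) {
      stopifnot(plant_individuals > 0, plant_individuals <= 1)
      sample(ped$individual_id, ceiling(plant_individuals * n))
    } else {
      plant_individuals %||% ped$individual_id
    }
    rows <- match(ids, ped$individual_id)
    if (anyNA(rows)) abort("plant_individuals not all in pedigree")
    for (r in seq_len(nrow(plant))) {
      c_idx <- match(as.character(plant$chromosome[r]), chroms$chromosome)
      if (is.na(c_idx)) abort("plant chromosome not in map")
      lo <- plant$start_bp[r] - 1
      hi <- plant$end_bp[r]
      for (i in rows) {
        for (h in c("h1", "h2")) {
          haps[[i]][[c_idx]][[h]] <-
            hap_overwrite(haps[[i]][[c_idx]][[h]], lo, hi, 1L)
        }
      }
    }
  }

  # genotype emission
  m <- nrow(map$markers)
  calls <- matrix(NA_integer_, n, m)
  col_of_chrom <- split(seq_len(m), factor(map$markers$chromosome,
                                           levels = chroms$chromosome))
  for (c in seq_len(n_chr)) {
    cols <- col_of_chrom[[c]]
    pos <- map$markers$position_bp[cols]
    for (i in seq_len(n)) {
      l1 <- hap_labels_at(haps[[i]][[c]]$h1, pos)
      l2 <- hap_labels_at(haps[[i]][[c]]$h2, pos)
      calls[i, cols] <- founders$alleles[cbind(l1, cols)] +
        founders$alleles[cbind(l2, cols)]
    }
  }

  # truth segments and realized autozygosity
  genome_bp <- sum(chroms$length_bp)
  seg_list <- vector("list", n)
  realized <- numeric(n)
  for (i in seq_len(n)) {
    per_chr <- lapply(seq_len(n_chr), function(c) {
      iv <- autozygous_intervals(haps[[i]][[c]]$h1, haps[[i]][[c]]$h2)
      if (is.null(iv)) return(NULL)
      tibble::tibble(
        individual_id = ped$individual_id[i],
        chromosome = chroms$chromosome[c],
        start_bp = as.integer(floor(iv[, "start"])) + 1L,
        end_bp = as.integer(floor(iv[, "end"])),
        exact_length = iv[, "end"] - iv[, "start"]
      )
    })
    segs <- dplyr::bind_rows(per_chr)
    realized[i] <- if (nrow(segs)) sum(segs$exact_length) / genome_bp else 0
    seg_list[[i]] <- segs
  }
  segments <- dplyr::bind_rows(seg_list)
  if (!nrow(segments)) {
    segments <- tibble::tibble(
      individual_id = character(), chromosome = character(),
      start_bp = integer(), end_bp = integer(), exact_length = numeric()
    )
  }

  # genotyping error / missingness injectors
  if (error_rate > 0) {
    hit <- which(runif(length(calls)) < error_rate & !is.na(calls))
    if (length(hit)) {
      shift <- sample(1:2, length(hit), replace = TRUE)
      calls[hit] <- (calls[hit] + shift) %% 3L
    }
  }
  if (missing_rate > 0) {
    calls[runif(length(calls)) < missing_rate] <- NA_integer_
  }

  markers <- tibble::tibble(
    chromosome = map$markers$chromosome,
    marker_id = map$markers$marker_id,
    position_bp = map$markers$position_bp,
    allele_a1 = "A", allele_a2 = "B"
  )
  samples <- tibble::tibble(
    individual_id = ped$individual_id,
    family_id = ped$individual_id,
    generation = ped$generation
  )
  gm <- genotypes(calls, markers, samples)

  truth_ind <- dplyr::left_join(
    expected_f_pedigree(ped),
    tibble::tibble(individual_id = ped$individual_id, realized_f = realized),
    by = "individual_id"
  )
  list(
    genotypes = gm,
    truth = list(segments = segments, individuals = truth_ind,
                 pedigree = ped, map = map)
  )
}

# overwrite (lo, hi] of a haplotype with a single label
hap_overwrite <- function(hap, lo, hi, lab) {
  L <- hap$ends[length(hap$ends)]
  pieces <- list()
  if (lo > 0) pieces <- c(pieces, list(hap_extract(hap, 0, lo)))
  pieces <- c(pieces, list(list(ends = min(hi, L), labs = lab)))
  if (hi < L) pieces <- c(pieces, list(hap_extract(hap, hi, L)))
  hap_merge_runs(list(
    ends = unlist(lapply(pieces, `[[`, "ends")),
    labs = unlist(lapply(pieces, `[[`, "labs"))
  ))
}

#' Deterministic toy dataset with known autozygosity
#'
#' A small four-generation pedigree (42 birds) genotyped on a 5 x 7 Mb map
#' at 60K-chip-like density (57 SNPs/Mb, 1,995 markers), with full-sib
#' matings in the later generations and one planted 5 Mb autozygous segment
#' on chromosome 2 of individual `G3_01`. Regeneration is byte-identical:
#' every draw is a pure function of the fixed seed.
#'
#' @param dir optional directory: writes PLINK BED/BIM/FAM and PED/MAP
#'   (prefix `toy`), a truth-segment TSV and a pedigree TSV.
#' @param seed integer seed (default fixed).
#' @return As [gene_drop()] (list of `genotypes` and `truth`).
#' @export
make_toy_fixture <- function(dir = NULL, seed = 20240425) {
  map <- recomb_map(stats::setNames(rep(7, 5), as.character(1:5)))
  ped <- toy_pedigree()
  founders <- simulate_founders(8, map, seed = seed)
  sim <- gene_drop(
    ped, founders,
    plant = tibble::tibble(chromosome = "2", start_bp = 1000001L,
                           end_bp = 6000000L),
    plant_individuals = "G3_01"
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    prefix <- file.path(dir, "toy")
    write_plink(sim$genotypes, prefix, format = "bed")
    write_plink(sim$genotypes, prefix, format = "ped")
    readr::write_tsv(sim$truth$segments, file.path(dir, "toy_truth_segments.tsv"))
    readr::write_tsv(sim$truth$pedigree, file.path(dir, "toy_pedigree.tsv"))
  }
  sim
}

#' Replicate-family pedigrees for parameter recovery
#'
#' Builds a pedigree of `n_families` independent families of a given
#' mating design, each contributing one offspring with a known expected
#' inbreeding coefficient: `"unrelated"` (F = 0), `"half_sib"` (parents are
#' half sibs, F = 0.125), `"full_sib"` (parents are full sibs, F = 0.25) or
#' `"selfing"` (one founder selfed, F = 0.5). Families share no founders,
#' so offspring are independent Monte-Carlo replicates.
#'
#' @param design mating design (see above).
#' @param n_families number of independent families / offspring.
#' @return A list: `pedigree` (a [pedigree()]), `offspring` (character ids),
#'   `expected_f` (the design's coefficient), `n_founders` needed.
#' @export
validation_pedigree <- function(design = c("unrelated", "half_sib",
                                           "full_sib", "selfing"),
                                n_families = 500) {
  design <- match.arg(design)
  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    tag <- sprintf("%s_%04d", design, f)
    rows[[f]] <- switch(
      design,
      unrelated = tibble::tibble(
        individual_id = paste0(tag, c("_S", "_D", "_O")),
        sire_id = c(NA, NA, paste0(tag, "_S")),
        dam_id = c(NA, NA, paste0(tag, "_D"))
      ),
      half_sib = tibble::tibble(
        # one sire, two dams; the two half-sib daughters are mated
        individual_id = paste0(tag, c("_A", "_B", "_C", "_H1", "_H2", "_O")),
        sire_id = c(NA, NA, NA, paste0(tag, "_A"), paste0(tag, "_A"),
                    paste0(tag, "_H1")),
        dam_id = c(NA, NA, NA, paste0(tag, "_B"), paste0(tag, "_C"),
                   paste0(tag, "_H2"))
      ),
      full_sib = tibble::tibble(
        individual_id = paste0(tag, c("_A", "_B", "_X", "_Y", "_O")),
        sire_id = c(NA, NA, paste0(tag, "_A"), paste0(tag, "_A"),
                    paste0(tag, "_X")),
        dam_id = c(NA, NA, paste0(tag, "_B"), paste0(tag, "_B"),
                   paste0(tag, "_Y"))
      ),
      selfing = tibble::tibble(
        individual_id = paste0(tag, c("_A", "_O")),
        sire_id = c(NA, paste0(tag, "_A")),
        dam_id = c(NA, paste0(tag, "_A"))
      )
    )
  }
  all <- dplyr::bind_rows(rows)
  ped <- pedigree(all$individual_id, all$sire_id, all$dam_id)
  list(
    pedigree = ped,
    offspring = ped$individual_id[endsWith(ped$individual_id, "_O")],
    expected_f = c(unrelated = 0, half_sib = 0.125, full_sib = 0.25,
                   selfing = 0.5)[[design]],
    n_founders = sum(is.na(ped$sire_id))
  )
}

toy_pedigree <- function() {
  f <- sprintf("F%02d", 1:8)
  ped <- tibble::tibble(
    individual_id = f, sire_id = NA_character_, dam_id = NA_character_
  )
  g1 <- tibble::tibble(
    individual_id = sprintf("G1_%02d", 1:10),
    sire_id = f[c(1, 1, 1, 3, 3, 3, 5, 5, 7, 7)],
    dam_id = f[c(2, 2, 2, 4, 4, 4, 6, 6, 8, 8)]
  )
  # G2_01..04 come from full-sib matings (F = 0.25); the rest from
  # crosses between unrelated gen-1 families
  g2 <- tibble::tibble(
    individual_id = sprintf("G2_%02d", 1:12),
    sire_id = c("G1_01", "G1_01", "G1_04", "G1_04", "G1_03", "G1_03",
                "G1_06", "G1_06", "G1_08", "G1_08", "G1_10", "G1_10"),
    dam_id = c("G1_02", "G1_02", "G1_05", "G1_05", "G1_07", "G1_07",
               "G1_09", "G1_09", "G1_09", "G1_09", "G1_07", "G1_07")
  )
  g3 <- tibble::tibble(
    individual_id = sprintf("G3_%02d", 1:12),
    sire_id = c("G2_01", "G2_01", "G2_03", "G2_03", "G2_05", "G2_05",
                "G2_07", "G2_07", "G2_09", "G2_09", "G2_11", "G2_11"),
    dam_id = c("G2_02", "G2_02", "G2_04", "G2_04", "G2_06", "G2_06",
               "G2_08", "G2_08", "G2_10", "G2_10", "G2_12", "G2_12")
  )
  all <- dplyr::bind_rows(ped, g1, g2, g3)
  pedigree(all$individual_id, all$sire_id, all$dam_id)
}
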