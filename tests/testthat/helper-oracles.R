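# Independent brute-force oracles and small fixture builders.
# These deliberately use naive, explicit enumeration so they share no code
# path with the package implementation.

# exact HWE p-value by enumerating every heterozygote configuration with
# the observed allele counts and summing the (multinomially weighted)
# probabilities no larger than the observed one
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het
  n_b <- 2 * n - n_a
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- sapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    factorial(n) / (factorial(hom_rare) * factorial(h) * factorial(hom_common)) *
      2^h
  })
  p <- w / sum(w)
  obs <- p[hets == n_het]
  sum(p[p <= obs * (1 + 1e-9)])
}

# window-by-window re-implementation of the sliding-window ROH scan with
# every window materialized explicitly
oracle_roh <- function(gm, params) {
  W <- params$window_snps
  res <- list()
  for (chr in unique(gm$markers$chromosome)) {
    cols <- which(gm$markers$chromosome == chr)
    m <- length(cols)
    if (m < W) next
    pos <- gm$markers$position_bp[cols]
    for (s in seq_len(nrow(gm$calls))) {
      g <- gm$calls[s, cols]
      nwin <- m - W + 1
      qual <- logical(nwin)
      for (j in seq_len(nwin)) {
        win <- g[j:(j + W - 1)]
        qual[j] <- sum(win == 1, na.rm = TRUE) <= params$window_het_max &&
          sum(is.na(win)) <= params$window_missing_max
      }
      cand <- logical(m)
      for (i in seq_len(m)) {
        js <- which(seq_len(nwin) <= i & seq_len(nwin) + W - 1 >= i)
        cand[i] <- mean(qual[js]) >= params$window_threshold
      }
      # walk candidate markers, breaking at non-candidates and big gaps
      run <- integer(0)
      flush <- function(run) {
        if (!length(run)) return(NULL)
        len <- pos[run[length(run)]] - pos[run[1]]
        if (len >= params$min_length_kb * 1000 &&
            length(run) >= params$min_snps) {
          data.frame(
            individual_id = rownames(gm$calls)[s], chromosome = chr,
            start_bp = pos[run[1]], end_bp = pos[run[length(run)]],
            n_snps = length(run), length_bp = len,
            stringsAsFactors = FALSE
          )
        } else NULL
      }
      for (i in seq_len(m)) {
        if (!cand[i]) {
          res[[length(res) + 1]] <- flush(run); run <- integer(0)
        } else {
          if (length(run) &&
              pos[i] - pos[run[length(run)]] > params$max_gap_kb * 1000) {
            res[[length(res) + 1]] <- flush(run); run <- integer(0)
          }
          run <- c(run, i)
        }
      }
      res[[length(res) + 1]] <- flush(run)
    }
  }
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(individual_id = character(), chromosome = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer())
  }
  res
}

# random genotype fixture with planted heterozygous/missing calls and
# occasional large inter-marker gaps
random_roh_fixture <- function(n_ind = 3, n_markers = 120, n_chrom = 2,
                               p_het = 0.05, p_miss = 0.03, p_gap = 0.02) {
  per_chr <- ceiling(n_markers / n_chrom)
  markers <- do.call(rbind, lapply(seq_len(n_chrom), function(c) {
    steps <- ifelse(runif(per_chr) < p_gap, 2e6, round(runif(per_chr, 5e3, 4e4)))
    data.frame(
      chromosome = as.character(c),
      marker_id = sprintf("c%d_m%d", c, seq_len(per_chr)),
      position_bp = as.integer(cumsum(steps))
    )
  }))
  m <- nrow(markers)
  calls <- matrix(sample(c(0L, 2L), n_ind * m, replace = TRUE), n_ind, m)
  calls[runif(n_ind * m) < p_het] <- 1L
  calls[runif(n_ind * m) < p_miss] <- NA_integer_
  genotypes(calls, markers,
            data.frame(individual_id = sprintf("ind%d", seq_len(n_ind))))
}

# genotypes object from a plain call matrix with evenly spaced markers
toy_genotypes <- function(calls, spacing_bp = 20000, chromosome = "1",
                          start_bp = spacing_bp) {
  calls <- rbind(calls)
  m <- ncol(calls)
  genotypes(
    calls,
    data.frame(chromosome = chromosome, marker_id = sprintf("m%d", 1:m),
               position_bp = as.integer(seq(start_bp, by = spacing_bp,
                                            length.out = m))),
    data.frame(individual_id = sprintf("ind%d", seq_len(nrow(calls))))
  )
}

expect_same_segments <- function(got, want) {
  attr(got, "params") <- NULL
  got <- as.data.frame(got)[, c("individual_id", "chromosome", "start_bp",
                                "end_bp", "n_snps", "length_bp")]
  want <- as.data.frame(want)
  ord <- function(d) d[order(d$individual_id, d$chromosome, d$start_bp), ,
                       drop = FALSE]
  got <- ord(got); rownames(got) <- NULL
  want <- ord(want); rownames(want) <- NULL
  got$start_bp <- as.integer(got$start_bp); want$start_bp <- as.integer(want$start_bp)
  got$end_bp <- as.integer(got$end_bp); want$end_bp <- as.integer(want$end_bp)
  got$n_snps <- as.integer(got$n_snps); want$n_snps <- as.integer(want$n_snps)
  got$length_bp <- as.integer(got$length_bp); want$length_bp <- as.integer(want$length_bp)
  expect_equal(got, want)
}
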