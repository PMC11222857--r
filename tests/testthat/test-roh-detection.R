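test_that("Lencz minimum window size evaluates and rounds as specified", {
  expect_identical(min_window_snps(1000, 100, 0.5), 21L)
  expect_identical(min_window_snps(53872, 651, 0.34), 49L)
  expect_identical(min_window_snps(1, 1, 0.5, alpha = 0.999), 1L)
  expect_error(min_window_snps(1000, 100, 1.2), "mean_het")
  expect_error(min_window_snps(1000, 100, 0.5, alpha = 0), "alpha")
})

test_that("an unbroken homozygous stretch is called as one segment", {
  # 60 homozygous markers spanning ~2 Mb
  gm <- toy_genotypes(matrix(2L, 1, 60), spacing_bp = 33000)
  p <- roh_params(window_snps = 10, min_snps = 10)
  segs <- detect_roh(gm, p)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_snps, 60L)
  expect_identical(segs$start_bp, gm$markers$position_bp[1])
  expect_identical(segs$end_bp, gm$markers$position_bp[60])
})

test_that("a large gap splits a run and short halves are dropped", {
  pos <- c(seq(33000, by = 33000, length.out = 30),
           seq(33000 * 30 + 1.6e6, by = 33000, length.out = 30))
  gm <- genotypes(
    matrix(2L, 1, 60),
    data.frame(chromosome = "1", marker_id = sprintf("m%d", 1:60),
               position_bp = as.integer(pos)),
    data.frame(individual_id = "ind1")
  )
  p <- roh_params(window_snps = 10, min_snps = 10)
  segs <- detect_roh(gm, p)
  expect_identical(nrow(segs), 0L)  # both halves just under 1 Mb
  expect_same_segments(segs, oracle_roh(gm, p))

  # with a lower length floor both halves survive as separate runs
  p2 <- roh_params(window_snps = 10, min_snps = 10, min_length_kb = 900)
  segs2 <- detect_roh(gm, p2)
  expect_identical(nrow(segs2), 2L)
  expect_same_segments(segs2, oracle_roh(gm, p2))
})

test_that("all-heterozygous individuals yield no segments", {
  gm <- toy_genotypes(matrix(1L, 2, 80))
  expect_identical(nrow(detect_roh(gm, roh_params(window_snps = 10))), 0L)
})

test_that("chromosomes shorter than the window yield no calls", {
  gm <- toy_genotypes(matrix(2L, 1, 30))
  expect_identical(nrow(detect_roh(gm, roh_params(window_snps = 49))), 0L)
})

test_that("unsorted markers are a precondition error", {
  gm <- toy_genotypes(matrix(2L, 1, 30))
  gm$markers$position_bp <- rev(gm$markers$position_bp)
  expect_error(detect_roh(gm, roh_params(window_snps = 10)), "sorted")
})

test_that("detector equals the brute-force window oracle on random fixtures", {
  set.seed(424)
  for (i in 1:60) {
    gm <- random_roh_fixture(
      n_ind = sample(1:4, 1), n_markers = sample(60:200, 1),
      n_chrom = sample(1:3, 1),
      p_het = runif(1, 0, 0.15), p_miss = runif(1, 0, 0.1)
    )
    W <- sample(c(5L, 8L, 12L), 1)
    p <- roh_params(
      window_snps = W, window_het_max = sample(0:2, 1),
      window_missing_max = sample(0:5, 1),
      window_threshold = sample(c(0.05, 0.3, 1), 1),
      min_length_kb = sample(c(100, 500, 1000), 1),
      min_snps = sample(c(W, 25L), 1)
    )
    expect_same_segments(detect_roh(gm, p), oracle_roh(gm, p))
  }
})

test_that("every emitted segment satisfies its own filters", {
  set.seed(99)
  gm <- random_roh_fixture(n_ind = 6, n_markers = 200, p_het = 0.04)
  p <- roh_params(window_snps = 10, min_snps = 15, min_length_kb = 300)
  segs <- detect_roh(gm, p)
  expect_true(all(segs$length_bp >= 300 * 1000))
  expect_true(all(segs$n_snps >= 15))
  expect_true(all(segs$end_bp >= segs$start_bp))
  # non-overlap within individual and chromosome
  by_ic <- split(segs, paste(segs$individual_id, segs$chromosome))
  for (d in by_ic) {
    d <- d[order(d$start_bp), ]
    if (nrow(d) > 1) expect_true(all(d$start_bp[-1] > d$end_bp[-nrow(d)]))
  }
})

test_that("raising the threshold or length floor never adds called length", {
  set.seed(7)
  gm <- random_roh_fixture(n_ind = 5, n_markers = 180, p_het = 0.05)
  total <- function(p) sum(detect_roh(gm, p)$length_bp)
  base <- roh_params(window_snps = 8, min_snps = 8, min_length_kb = 200)
  expect_lte(total(roh_params(window_snps = 8, min_snps = 8,
                              min_length_kb = 200, window_threshold = 0.5)),
             total(base))
  expect_lte(total(roh_params(window_snps = 8, min_snps = 8,
                              min_length_kb = 600)),
             total(base))
})

test_that("planted autozygous segments are recovered despite genotyping error", {
  map <- recomb_map(c(`1` = 12, `2` = 12))
  ped <- pedigree(sprintf("I%02d", 1:20))
  fp <- simulate_founders(20, map, seed = 31)
  sim <- gene_drop(ped, fp, error_rate = 0.002,
                   plant = tibble::tibble(chromosome = "2", start_bp = 3000001L,
                                          end_bp = 8000000L),
                   plant_individuals = sprintf("I%02d", 1:10))
  segs <- detect_roh(sim$genotypes, roh_params())
  carriers <- sprintf("I%02d", 1:10)
  hits <- segs[segs$chromosome == "2" & segs$individual_id %in% carriers, ]
  recovered <- vapply(carriers, function(id) {
    h <- hits[hits$individual_id == id, ]
    if (!nrow(h)) return(0)
    ov <- pmin(h$end_bp, 8000000) - pmax(h$start_bp, 3000001)
    max(ov) / 5e6
  }, numeric(1))
  expect_true(all(recovered >= 0.9))
})

test_that("length classes follow left-closed binning", {
  expect_identical(as.character(roh_length_class(1.441e6)), "1-2")
  expect_identical(as.character(roh_length_class(2.0e6)), "2-4")
  expect_identical(as.character(roh_length_class(33.47e6)), ">16")
  expect_true(is.na(roh_length_class(0.9e6)))
  expect_identical(as.character(roh_length_class(c(4e6, 8e6, 16e6))),
                   c("4-8", "8-16", ">16"))
})

test_that("ROH recovery tracks expected F across a pedigree gradient", {
  # dense map, no genotyping error: per-individual called length close to
  # true autozygous length, and mean F_ROH ordered with pedigree F
  map <- recomb_map(c(`1` = 30, `2` = 30), snps_per_mb = 60)
  means <- c()
  for (d in c("unrelated", "full_sib", "selfing")) {
    vp <- validation_pedigree(d, 40)
    fp <- simulate_founders(vp$n_founders, map, seed = 77)
    sim <- gene_drop(vp$pedigree, fp)
    off <- match(vp$offspring, sim$genotypes$samples$individual_id)
    gm <- sim$genotypes[off, ]
    segs <- detect_roh(gm)
    fr <- f_roh(segs, l_auto = sum(map$chrom$length_bp),
                individuals = gm$samples)
    tr <- sim$truth$individuals
    tr <- tr[match(vp$offspring, tr$individual_id), ]
    expect_lt(mean(abs(fr$f_roh - tr$realized_f)), 0.02)
    means[d] <- mean(fr$f_roh)
  }
  expect_true(means["unrelated"] < means["full_sib"])
  expect_true(means["full_sib"] < means["selfing"])
})
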