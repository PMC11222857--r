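single_marker_gm <- function(calls_vec, spacing = 1e6) {
  toy_genotypes(matrix(calls_vec, ncol = 1), spacing_bp = spacing)
}

test_that("F_ROH follows segment totals and genome length", {
  segs <- tibble::tibble(individual_id = "a", chromosome = "1",
                         start_bp = 1L, end_bp = 134120001L,
                         n_snps = 100L, length_bp = 134.12e6)
  expect_equal(f_roh(segs, l_auto = 0.94e9)$f_roh, 0.1427, tolerance = 1e-3)
  expect_equal(round(f_roh(segs, l_auto = 0.94e9)$f_roh, 3), 0.143)

  expect_equal(f_roh(segs[0, ], individuals = "a")$f_roh, 0)
  segs$length_bp <- 0.94e9
  expect_equal(f_roh(segs, l_auto = 0.94e9)$f_roh, 1)
  segs$length_bp <- -5
  expect_error(f_roh(segs), "negative")
})

test_that("per-class F_ROH decomposes the overall coefficient", {
  set.seed(2)
  lengths <- runif(40, 1e6, 30e6)
  segs <- tibble::tibble(
    individual_id = sample(c("a", "b", "c"), 40, replace = TRUE),
    chromosome = "1", start_bp = 1L, end_bp = 2L, n_snps = 50L,
    length_bp = lengths, length_class = roh_length_class(lengths)
  )
  r <- f_roh(segs, l_auto = 1e9, by_class = TRUE,
             individuals = c("a", "b", "c", "d"))
  class_sum <- rowSums(r[, grep("^f_roh_", names(r))])
  expect_equal(class_sum, r$f_roh, tolerance = 1e-12)
  expect_equal(r$f_roh[r$individual_id == "d"], 0)
  expect_true(all(r$f_roh >= 0 & r$f_roh <= 1))
})

test_that("F_GRM reproduces hand-evaluated cases exactly", {
  # single marker p = 0.5 (calls 2,1,1,0 give p = 0.5)
  gm <- single_marker_gm(c(2L, 1L, 1L, 0L))
  f <- f_grm(gm)$f_grm
  expect_equal(f[1], 1.0, tolerance = 1e-12)   # x = 2
  expect_equal(f[2], -1.0, tolerance = 1e-12)  # x = 1
  expect_equal(f[4], 1.0, tolerance = 1e-12)   # x = 0 (symmetry)

  # two markers p = 0.25 each, individual with x = (0, 0): -1/3
  calls <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 0L), c(1L, 1L))
  gm2 <- toy_genotypes(calls)  # p = 0.25 per marker
  f2 <- f_grm(gm2)$f_grm
  expect_equal(f2[1], -1 / 3, tolerance = 1e-12)

  # mean_of_ratios agrees on a single marker
  expect_equal(f_grm(gm, variant = "mean_of_ratios")$f_grm,
               f_grm(gm)$f_grm, tolerance = 1e-12)
  expect_error(f_grm(single_marker_gm(c(2L, 2L, 2L))), "monomorphic")
})

test_that("F_HOM reproduces hand-evaluated cases exactly", {
  # two markers, p = 0.5 at both
  calls <- rbind(c(2L, 2L), c(1L, 1L), c(0L, 0L), c(1L, 1L))
  f <- f_hom(toy_genotypes(calls))$f_hom
  expect_equal(f[1], 1.0, tolerance = 1e-12)   # both homozygous
  expect_equal(f[2], -1.0, tolerance = 1e-12)  # both heterozygous

  # fully homozygous individual is exactly 1 at any frequencies
  set.seed(8)
  calls2 <- matrix(sample(0:2, 10 * 20, replace = TRUE, prob = c(.2, .5, .3)),
                   10, 20)
  calls2[1, ] <- sample(c(0L, 2L), 20, replace = TRUE)
  expect_equal(f_hom(toy_genotypes(calls2))$f_hom[1], 1.0, tolerance = 1e-12)
})

test_that("F_UNI reproduces hand-evaluated cases exactly", {
  gm <- single_marker_gm(c(2L, 1L, 1L, 0L))  # p = 0.5
  f <- f_uni(gm)$f_uni
  expect_equal(f[1], 1.0, tolerance = 1e-12)
  expect_equal(f[2], -1.0, tolerance = 1e-12)
  expect_equal(f[4], 1.0, tolerance = 1e-12)
})

test_that("all four estimators are invariant to allele-label flips", {
  set.seed(10)
  calls <- matrix(sample(c(0:2, NA), 30 * 60, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 30, 60)
  gm <- toy_genotypes(calls)
  gmf <- toy_genotypes(2L - calls)
  expect_equal(f_grm(gm)$f_grm, f_grm(gmf)$f_grm, tolerance = 1e-12)
  expect_equal(f_hom(gm)$f_hom, f_hom(gmf)$f_hom, tolerance = 1e-12)
  expect_equal(f_uni(gm)$f_uni, f_uni(gmf)$f_uni, tolerance = 1e-12)
})

test_that("population mean of F_HOM is near zero under HWE sampling", {
  set.seed(20)
  n <- 400; m <- 500
  p <- runif(m, 0.1, 0.5)
  calls <- sapply(p, function(pj) rbinom(n, 2, pj))
  f <- f_hom(toy_genotypes(calls))$f_hom
  expect_lt(abs(mean(f)), 3 * sd(f) / sqrt(n) + 0.005)
})

test_that("missing calls adapt numerators and denominators per individual", {
  calls <- rbind(c(2L, 1L, NA), c(0L, 1L, 2L), c(1L, 1L, 0L), c(2L, 0L, 1L))
  gm <- toy_genotypes(calls)
  p <- allele_freqs(gm)
  # individual 1 by hand over its two non-missing markers
  x <- calls[1, 1:2]
  expect_equal(
    f_grm(gm)$f_grm[1],
    sum((x - 2 * p[1:2])^2) / (2 * sum(p[1:2] * (1 - p[1:2]))) - 1,
    tolerance = 1e-12
  )
  e_hom <- sum(1 - 2 * p[1:2] * (1 - p[1:2]))
  expect_equal(f_hom(gm)$f_hom[1],
               (sum(x != 1) - e_hom) / (2 - e_hom), tolerance = 1e-12)
})

test_that("estimator correlations behave like Pearson correlation", {
  rec <- tibble::tibble(
    individual_id = letters[1:3],
    f_roh = c(1, 2, 3), f_dup = c(1, 2, 3), f_neg = c(-1, -2, -3),
    f_other = c(2, 4, 7)
  )
  r <- estimator_correlations(rec)
  expect_equal(unclass(r)["f_roh", "f_dup"], 1)
  expect_equal(unclass(r)["f_roh", "f_neg"], -1)
  expect_equal(unclass(r)["f_roh", "f_other"],
               cor(c(1, 2, 3), c(2, 4, 7)))
  expect_equal(diag(unclass(r)), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unclass(r), t(unclass(r)))

  expect_error(estimator_correlations(rec[1:2, ]), "at least 3")
  rec$f_const <- 1
  expect_warning(estimator_correlations(rec), "zero-variance")

  td <- tidy(r)
  expect_identical(nrow(td), 16L)
  expect_equal(td$r[td$estimator1 == "f_roh" & td$estimator2 == "f_neg"], -1)
})

test_that("generation trends equal stratified recomputation", {
  rec <- tibble::tibble(
    individual_id = c("a", "b", "c", "d"),
    f_roh = c(0.1, 0.2, 0.3, 0.4), f_grm = c(0, 0.1, -0.1, 0.2)
  )
  samples <- tibble::tibble(individual_id = c("a", "b", "c", "d"),
                            generation = c(1L, 1L, 2L, 2L))
  tr <- generation_trend(rec, samples)
  expect_equal(tr$f_roh, c(0.15, 0.35))
  expect_equal(tr$f_grm, c(0.05, 0.05))

  # constant coefficients give a flat trend
  rec$f_roh <- 0.2
  expect_equal(unique(generation_trend(rec, samples)$f_roh), 0.2)
})

test_that("estimators regress on truth in gene-drop simulations", {
  map <- recomb_map(c(`1` = 25, `2` = 25), snps_per_mb = 60)
  recs <- list(); truths <- list()
  for (d in c("unrelated", "half_sib", "full_sib", "selfing")) {
    vp <- validation_pedigree(d, 30)
    fp <- simulate_founders(vp$n_founders, map, seed = 88)
    sim <- gene_drop(vp$pedigree, fp)
    off <- match(vp$offspring, sim$genotypes$samples$individual_id)
    gm <- sim$genotypes[off, ]
    segs <- detect_roh(gm)
    ib <- compute_inbreeding(gm, segs, l_auto = sum(map$chrom$length_bp))
    tr <- sim$truth$individuals
    recs[[d]] <- ib
    truths[[d]] <- tr[match(vp$offspring, tr$individual_id), ]
  }
  ib <- dplyr::bind_rows(recs)
  tr <- dplyr::bind_rows(truths)
  m <- dplyr::inner_join(ib, tr, by = "individual_id")
  # slope of F_ROH on expected F close to 1 (dense map, no error)
  slope <- coef(lm(f_roh ~ expected_f, data = m))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
  for (col in c("f_roh", "f_grm", "f_hom", "f_uni")) {
    expect_gt(cor(m[[col]], m$expected_f, method = "spearman"), 0)
  }
})
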