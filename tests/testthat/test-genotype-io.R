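test_that("PLINK binary round-trip preserves calls, marker and sample order", {
  set.seed(7)
  n <- 20; m <- 50
  calls <- matrix(sample(c(0:2, NA), n * m, replace = TRUE), n, m)
  gm <- genotypes(
    calls,
    data.frame(chromosome = rep(c("1", "2"), each = m / 2),
               marker_id = sprintf("snp%02d", 1:m),
               position_bp = rep(seq(1e4, by = 1e4, length.out = m / 2), 2),
               allele_a1 = "A", allele_a2 = "C"),
    data.frame(individual_id = sprintf("id%02d", 1:n))
  )
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(gm, prefix, format = "bed")
  back <- read_plink_binary(prefix)
  expect_identical(unname(back$calls), unname(gm$calls))
  expect_identical(back$markers$marker_id, gm$markers$marker_id)
  expect_identical(back$markers$allele_a1, gm$markers$allele_a1)
  expect_identical(back$samples$individual_id, gm$samples$individual_id)
})

test_that("all-homozygous and single-het fixtures decode as expected", {
  gm <- toy_genotypes(matrix(2L, 2, 3))
  prefix <- file.path(withr::local_tempdir(), "homo")
  write_plink(gm, prefix, format = "bed")
  expect_true(all(read_plink_binary(prefix)$calls == 2L))

  calls <- matrix(2L, 2, 3); calls[1, 2] <- 1L
  gm2 <- toy_genotypes(calls)
  write_plink(gm2, prefix, format = "bed")
  expect_identical(sum(read_plink_binary(prefix)$calls == 1L), 1L)
})

test_that("bad magic bytes and truncated payloads are rejected", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "bad")
  write_plink(toy_genotypes(matrix(2L, 2, 3)), prefix, format = "bed")
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  raw[1] <- as.raw(0xff)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(read_plink_binary(prefix), "magic")

  write_plink(toy_genotypes(matrix(2L, 2, 3)), prefix, format = "bed")
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  writeBin(raw[-length(raw)], paste0(prefix, ".bed"))
  expect_error(read_plink_binary(prefix), "integrity")
})

test_that("PED/MAP text decoding handles alleles and missing genotypes", {
  dir <- withr::local_tempdir()
  writeLines("F1 I1 0 0 1 -9 A A C C", file.path(dir, "t.ped"))
  writeLines(c("1\tm1\t0\t1000", "1\tm2\t0\t2000"), file.path(dir, "t.map"))
  gm <- read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_identical(unname(gm$calls[1, ]), c(2L, 2L))
  expect_identical(gm$markers$allele_a1, c("A", "C"))

  writeLines(c("F1 I1 0 0 1 -9 A A 0 0", "F2 I2 0 0 2 -9 A C C C"),
             file.path(dir, "t.ped"))
  gm <- read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_true(is.na(gm$calls[1, 2]))
  expect_identical(gm$calls[2, 1], 1L)

  writeLines(c("F1 I1 0 0 1 -9 A A", "F2 I2 0 0 1 -9 A A C C"),
             file.path(dir, "t.ped"))
  expect_error(read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map")),
               "ragged|mis-sized")
})

test_that("text and binary encodings of one fixture give identical genotypes", {
  set.seed(11)
  n <- 12; m <- 30
  # keep A1 strictly minor at every marker so text allele inference is exact
  calls <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                  n, m)
  calls[, colSums(calls) >= n] <- 0L
  calls[1, colSums(calls) == 0L] <- 1L
  gm <- toy_genotypes(calls)
  gm$markers$allele_a1 <- "G"
  gm$markers$allele_a2 <- "T"
  dir <- withr::local_tempdir()
  write_plink(gm, file.path(dir, "x"), format = "bed")
  write_plink(gm, file.path(dir, "x"), format = "ped")
  from_bed <- read_plink_binary(file.path(dir, "x"))
  from_ped <- read_plink_text(file.path(dir, "x.ped"), file.path(dir, "x.map"))
  expect_identical(unname(from_bed$calls), unname(from_ped$calls))
  expect_identical(from_bed$markers$allele_a1, from_ped$markers$allele_a1)
})

test_that("marker statistics match naive recounting", {
  gm <- toy_genotypes(matrix(c(2L, 2L, 2L, NA), 4, 1))
  gm <- compute_marker_stats(gm)
  expect_equal(gm$markers$call_rate, 0.75)
  expect_equal(gm$markers$maf, 0)

  gm <- compute_marker_stats(toy_genotypes(matrix(c(0L, 1L, 2L), 3, 1)))
  expect_equal(gm$markers$maf, 0.5)

  set.seed(3)
  calls <- matrix(sample(c(0:2, NA), 50 * 100, replace = TRUE), 50, 100)
  gm <- compute_marker_stats(toy_genotypes(calls))
  naive_maf <- apply(calls, 2, function(g) {
    g <- g[!is.na(g)]
    p <- sum(g) / (2 * length(g))
    min(p, 1 - p)
  })
  expect_equal(gm$markers$maf, naive_maf)
  expect_equal(gm$markers$call_rate, colMeans(!is.na(calls)))
})

test_that("flipping allele labels maps calls to 2-x and keeps maf and hwe_p", {
  set.seed(5)
  calls <- matrix(sample(c(0:2, NA), 30 * 40, replace = TRUE), 30, 40)
  gm <- compute_marker_stats(toy_genotypes(calls))
  flipped <- compute_marker_stats(toy_genotypes(2L - calls))
  expect_identical(2L - gm$calls, flipped$calls)
  expect_equal(gm$markers$maf, flipped$markers$maf)
  expect_equal(gm$markers$hwe_p, flipped$markers$hwe_p)
})

test_that("QC removes markers in fixed order and is idempotent", {
  markers <- data.frame(
    chromosome = c("Z", "1", "1", "1"),
    marker_id = sprintf("m%d", 1:4),
    position_bp = c(1000L, 1000L, 2000L, 3000L)
  )
  calls <- cbind(
    rep(2L, 30),                          # on Z: removed first
    c(rep(NA_integer_, 4), rep(2L, 26)),  # call rate 0.87
    rep(1L, 30),                          # all-het: extreme HWE departure
    rep_len(c(0L, 1L, 2L, 1L), 30)        # near-HWE polymorphic keeper
  )
  gm <- genotypes(calls, markers,
                  data.frame(individual_id = sprintf("i%d", 1:30)))
  res <- apply_qc(gm, qc_params())
  expect_identical(res$report$n_removed, c(1L, 1L, 1L, 0L))
  expect_identical(res$genotypes$markers$marker_id, "m4")

  again <- apply_qc(res$genotypes, qc_params())
  expect_identical(sum(again$report$n_removed), 0L)

  # MAF filter only removes when enabled
  gm2 <- compute_marker_stats(toy_genotypes(
    matrix(c(rep(2L, 19), 1L), 20, 1)  # maf 0.025
  ))
  expect_warning(
    res_maf <- apply_qc(gm2, qc_params(min_maf = 0.05)),
    "all markers removed"
  )
  expect_identical(nrow(res_maf$genotypes$markers), 0L)
  expect_identical(nrow(apply_qc(gm2, qc_params())$genotypes$markers), 1L)
})
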