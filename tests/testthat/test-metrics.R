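test_that("subsample_reads is uniform-without-replacement and seeded", {
  ids <- sprintf("r%04d", 1:500)
  expect_identical(subsample_reads(ids, 500, seed = 1), ids)
  expect_length(subsample_reads(ids, 0, seed = 1), 0L)
  s1 <- subsample_reads(ids, 100, seed = 100)
  s2 <- subsample_reads(ids, 100, seed = 100)
  expect_setequal(s1, s2)
  expect_identical(anyDuplicated(s1), 0L)
  expect_error(subsample_reads(ids, 501, seed = 1), "exceeds")
})

test_that("saturation arithmetic and limits", {
  expect_equal(saturation(10, 10), 0)
  expect_equal(saturation(10, 4), 0.6)
  expect_equal(saturation(10, 5), 0.5)
  expect_error(saturation(0, 0), "positive")
  expect_error(saturation(10, 11), "unique_counts")
})

test_that("saturation_curve deduplicates by (cell, gene, UMI) and plateaus", {
  # library with exactly 100 distinct molecules per cell, heavily resampled
  set.seed(41)
  n_cells <- 5
  mols <- do.call(rbind, lapply(seq_len(n_cells), function(c) {
    data.frame(cell_id = sprintf("c%d", c),
               gene = sample(sprintf("g%02d", 1:30), 100, replace = TRUE),
               umi = random_dna(100, 9))
  }))
  reads <- mols[sample(nrow(mols), 5000, replace = TRUE), ]
  curve <- saturation_curve(reads, c(1, 10, 100, 500, 1000), seed = 100)
  expect_true(all(curve$mean_umis <= 100))
  expect_true(all(diff(curve$mean_umis) >= 0))
  expect_true(all(diff(curve$mean_genes) >= 0))
  expect_true(all(curve$saturation >= 0 & curve$saturation <= 1))
  # depth 1/cell: nearly every read is a fresh molecule
  expect_lt(curve$saturation[1], 0.25)
  # deep point approaches the 100-molecule plateau
  expect_gt(curve$mean_umis[5], 90)
  expect_warning(saturation_curve(reads, c(1, 10^6), seed = 100),
                 "dropping")
  expect_error(saturation_curve(reads, c(10, 1), seed = 100), "ascending")
})

test_that("simulated libraries plateau at their true molecule count", {
  # 100 true molecules per cell: 20 genes x 5 counts each
  layout <- toy_layout(4, seed = 9)
  tx <- make_transcriptome(20, mito_fraction = 0, seed = 9)
  truth <- simulate_expression(layout, tx, seed = 9)
  truth$counts[] <- 5L
  sim <- simulate_reads(truth, layout, tx, depth_per_cell = 600, seed = 9)
  curve <- saturation_curve(sim$tags, c(1, 50, 200, 600), seed = 100)
  expect_true(all(curve$mean_umis <= 100))
  expect_gt(curve$mean_umis[4], 95)       # deep point near the plateau
  expect_lt(curve$saturation[1], 0.1)     # single-read limit
  expect_gt(curve$saturation[4], 0.8)     # 600 reads over 100 molecules
  # doubling depth never decreases mean UMIs/cell (paired-seed comparison)
  expect_true(all(diff(curve$mean_umis) >= 0))
})

test_that("dropout_ratio matches hand counts and brute force", {
  m <- rbind(absent = c(0, 0, 0, 0),
             everywhere = c(1, 2, 3, 4),
             partial = c(0, 0, 0, 5))
  colnames(m) <- sprintf("c%d", 1:4)
  d <- dropout_ratio(m)
  expect_equal(d$dropout, c(1, 0, 0.75))
  expect_error(dropout_ratio(m[, 0, drop = FALSE]), "matrix")
  set.seed(19)
  big <- matrix(rnbinom(600, mu = 0.8, size = 1), 30, 20,
                dimnames = list(sprintf("g%d", 1:30), sprintf("c%d", 1:20)))
  brute <- apply(big, 1, function(r) sum(r == 0) / length(r))
  expect_equal(dropout_ratio(big)$dropout, unname(brute))
})

test_that("per_cell_qc matches hand counts and column sums", {
  m <- rbind(geneA = c(2, 0), geneB = c(0, 0), MTC = c(3, 0))
  colnames(m) <- c("c1", "c2")
  qc <- per_cell_qc(m)
  expect_identical(qc$genes_detected, c(2L, 0L))
  expect_identical(qc$total_umis, c(5, 0))
  expect_equal(qc$percent_mito, c(60, NA_real_))
  set.seed(27)
  big <- matrix(rnbinom(800, mu = 2, size = 1), 40, 20,
                dimnames = list(sprintf("g%d", 1:40), sprintf("c%d", 1:20)))
  qc2 <- per_cell_qc(big, is_mito = rep(c(TRUE, FALSE), each = 20))
  expect_equal(qc2$total_umis, unname(colSums(big)))
  expect_equal(qc2$genes_detected, unname(apply(big, 2, function(x)
    sum(x > 0))))
})

test_that("count matrix round-trips through MTX and dense TSV", {
  set.seed(33)
  m <- matrix(rnbinom(200, mu = 3, size = 1), 20, 10,
              dimnames = list(c(sprintf("MT%02d", 1:4),
                                sprintf("G%02d", 5:20)),
                              sprintf("cell%02d", 1:10)))
  dir <- file.path(withr::local_tempdir(), "mtx")
  write_count_matrix(m, dir)
  back <- read_count_matrix(dir)
  expect_equal(unclass(back)[, ], m[, ])
  expect_identical(attr(back, "is_mito"), grepl("^MT", rownames(m)))
  dense <- file.path(withr::local_tempdir(), "m.tsv")
  write_tsv(data.frame(gene_id = rownames(m), m, check.names = FALSE), dense)
  back2 <- read_count_matrix(dense)
  expect_equal(unclass(back2)[, ], m[, ])
})

test_that("tcr_recovery applies the complete/productive/CDR3 filter", {
  rows <- rbind(
    data.frame(cell_id = "c1", locus = c("TRA", "TRB"), v_call = "V",
               j_call = "J", junction_aa = "CASS", productive = "TRUE"),
    data.frame(cell_id = "c2", locus = c("TRA", "TRB"), v_call = "V",
               j_call = "J", junction_aa = "CASS", productive = "True"),
    data.frame(cell_id = "c3", locus = "TRB", v_call = "V", j_call = "J",
               junction_aa = "CASS", productive = "T"))
  res <- tcr_recovery(rows, cells = c("c1", "c2", "c3", "c4"))
  expect_equal(res$pct_TRA, 50)
  expect_equal(res$pct_TRB, 75)
  expect_equal(res$pct_paired, 50)
  expect_identical(res$n_cells, 4L)
  # unproductive-only table
  unprod <- transform(rows, productive = "FALSE")
  res0 <- tcr_recovery(unprod, cells = c("c1", "c2", "c3"))
  expect_equal(res0$pct_TRA + res0$pct_TRB + res0$pct_paired, 0)
  # incomplete chains (missing CDR3) never qualify
  nocdr3 <- transform(rows, junction_aa = "")
  expect_equal(tcr_recovery(nocdr3, c("c1", "c2"))$pct_paired, 0)
  expect_error(tcr_recovery(rows, cells = character(0)), "empty")
})

test_that("pct_paired <= min(pct_TRA, pct_TRB) on random AIRR tables", {
  set.seed(55)
  for (k in seq_len(60)) {
    n <- sample(3:25, 1)
    cells <- sprintf("c%02d", seq_len(n))
    rows <- data.frame(
      cell_id = sample(cells, 2 * n, replace = TRUE),
      locus = sample(c("TRA", "TRB"), 2 * n, replace = TRUE),
      v_call = sample(c("V", ""), 2 * n, replace = TRUE),
      j_call = sample(c("J", ""), 2 * n, replace = TRUE),
      junction_aa = sample(c("CASS", ""), 2 * n, replace = TRUE),
      productive = sample(c(TRUE, FALSE), 2 * n, replace = TRUE))
    res <- tcr_recovery(rows, cells)
    expect_lte(res$pct_paired, min(res$pct_TRA, res$pct_TRB))
  }
})

test_that("recovery rate matches simulate_airr truth at scale", {
  layout <- make_layout(random_dna(24, 16, seed = 6), 1000, pool_size = 24)
  sim <- simulate_airr(layout, pair_rate = 0.8, alpha_only_rate = 0.05,
                       beta_only_rate = 0.05, unproductive_rate = 0.05,
                       seed = 12)
  res <- tcr_recovery(sim$airr, layout$wells$cell_id)
  se <- 100 * sqrt(0.8 * 0.2 / 1000)
  expect_lt(abs(res$pct_paired - 80), 3 * se)
  expect_equal(res$pct_paired,
               round(100 * mean(sim$truth$category == "paired"), 2))
})
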