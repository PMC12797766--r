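test_that("detect_concatemers flags junction literals exactly", {
  reads <- c(paste0(strrep("A", 40), "ATATGGGCTAC", strrep("C", 39)),
             strrep("A", 90),
             paste0("GTAGCCCATAT", strrep("G", 79)))
  res <- detect_concatemers(reads)
  expect_identical(res$flags, c(TRUE, FALSE, TRUE))
  expect_equal(res$fraction, 2 / 3)
  expect_error(detect_concatemers(reads, literals = "ATATGGG", k = 11),
               "length k")
  # a read and its reverse complement flag identically when both
  # orientations are listed
  rc <- revcomp(reads)
  expect_identical(detect_concatemers(rc)$flags, res$flags)
})

test_that("extract_5p_umi_reads agrees with a brute-force Hamming scan", {
  lit <- "ATTGCGCAATG"
  exact <- paste0(strrep("C", 5), lit, strrep("C", 10))
  one_off <- paste0(strrep("C", 5), "ATTGAGCAATG", strrep("C", 10))
  two_off <- paste0(strrep("C", 5), "ATTGAGCATTG", strrep("C", 10))
  expect_identical(extract_5p_umi_reads(c(exact, one_off, two_off)),
                   c(TRUE, TRUE, FALSE))
  expect_identical(extract_5p_umi_reads(two_off, hdist = 2), TRUE)

  brute <- function(r) {
    p <- nchar(lit)
    any(vapply(seq_len(nchar(r) - p + 1), function(o) {
      sum(strsplit(substr(r, o, o + p - 1), "")[[1]] !=
            strsplit(lit, "")[[1]]) <= 1
    }, logical(1)))
  }
  set.seed(31)
  reads <- random_dna(1000, 26)
  expect_identical(extract_5p_umi_reads(reads),
                   vapply(reads, brute, logical(1), USE.NAMES = FALSE))
})

test_that("dedup_5p_reads keeps one record per alignment key", {
  tags <- data.frame(cell_id = c("c1", "c1", "c1", "c2"),
                     umi = c("AAA", "AAA", "AAA", "AAA"),
                     ref = "g1", start = c(0L, 0L, 5L, 0L),
                     end = c(90L, 90L, 95L, 90L), strand = "+")
  dd <- dedup_5p_reads(tags)
  expect_identical(nrow(dd), 3L)
  # set-count oracle
  key <- with(tags, paste(cell_id, umi, ref, start, strand))
  expect_identical(nrow(dd), length(unique(key)))
})

test_that("invasion_pattern follows per-method UMI/spacer geometry", {
  expect_identical(invasion_pattern("ACGTACGTA", method_config("pb10x")),
                   "ACGTACGTATTTCTTATATGGG")
  expect_identical(nchar(invasion_pattern("ACGTACGTA",
                                          method_config("pb10x"))), 22L)
  expect_identical(nchar(invasion_pattern("ACGTACGTAC",
                                          method_config("tenx"))), 23L)
  # SS3X: 8-nt UMI + observed WW spacer from the extracted 10-mer
  expect_identical(invasion_pattern("ACGTACGTTA", method_config("ss3x")),
                   "ACGTACGTTAGGG")
  expect_error(invasion_pattern("ACGT", method_config("pb10x")), "length")
})

test_that("flag_strand_invasion matches the brute-force oracle", {
  cfg <- method_config("pb10x")
  set.seed(17)
  umis <- random_dna(150, 9)
  windows <- random_dna(150, sample(c(0, 5, 21, 22, 23, 26), 150,
                                    replace = TRUE))
  res <- flag_strand_invasion(umis, windows, cfg)
  pats <- invasion_pattern(umis, cfg)
  oracle <- mapply(oracle_best_hamming, pats, windows, USE.NAMES = FALSE)
  expect_identical(res$flag, !is.na(oracle) & oracle <= 3)
  expect_identical(res$best_mismatches,
                   ifelse(res$flag, oracle, NA_integer_))
})

test_that("mismatch boundary: 3 flagged, 4 not; degenerate windows unflagged", {
  cfg <- method_config("pb10x")
  umi <- "ACGTACGTA"
  pat <- invasion_pattern(umi, cfg)
  win0 <- paste0("A", pat)                      # pattern padded to 23
  r0 <- flag_strand_invasion(umi, win0, cfg)
  expect_true(r0$flag)
  expect_identical(r0$best_mismatches, 0L)
  # exactly 3 substitutions in the anchored copy: still flagged, load 3
  mut <- function(s, pos) {
    for (p in pos) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, p, p))[1]
    }
    s
  }
  win3 <- paste0("A", mut(pat, c(3, 10, 17)))
  r3 <- flag_strand_invasion(umi, win3, cfg)
  expect_true(r3$flag)
  expect_identical(r3$best_mismatches, 3L)
  # 4 substitutions with no compensating offset: verified by oracle, not
  # flagged
  win4 <- paste0("A", mut(pat, c(3, 7, 10, 17)))
  expect_gte(min(oracle_best_hamming(pat, win4), na.rm = TRUE), 4)
  expect_false(flag_strand_invasion(umi, win4, cfg)$flag)
  # contig start: empty window
  expect_false(flag_strand_invasion(umi, "", cfg)$flag)
})

test_that("monotonicity in max_mismatch and window length", {
  cfg <- method_config("pb10x")
  set.seed(23)
  umis <- random_dna(100, 9)
  wins <- random_dna(100, 23)
  pats <- invasion_pattern(umis, cfg)
  frac <- vapply(0:6, function(mm) {
    cfg2 <- cfg; cfg2$max_mismatch <- mm
    mean(flag_strand_invasion(umis, wins, cfg2)$flag)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  shrunk <- substr(wins, 2, 23)
  full <- flag_strand_invasion(umis, wins, cfg)$flag
  small <- flag_strand_invasion(umis, shrunk, cfg)$flag
  expect_true(all(!small | full))
})

test_that("edit mode admits indel matches that hamming mode rejects", {
  cfg <- method_config("pb10x")
  umi <- "ACGTACGTA"
  pat <- invasion_pattern(umi, cfg)
  # delete one base from the pattern: 1 edit, but many substitutions at
  # any anchored offset
  gapped <- paste0("AG", substr(pat, 1, 10), substr(pat, 12, 22))
  h <- flag_strand_invasion(umi, gapped, cfg, mode = "hamming")
  e <- flag_strand_invasion(umi, gapped, cfg, mode = "edit")
  expect_false(h$flag)
  expect_true(e$flag)
  expect_identical(e$best_mismatches, 1L)
})

test_that("upstream_context honours strand and contig edges", {
  ref <- c(g1 = paste0("TTTTTGGGGG", strrep("A", 40)))
  plus <- data.frame(cell_id = "c", umi = "AAACCCGGG", ref = "g1",
                     start = 10L, end = 30L, strand = "+")
  # 0-based start 10: upstream window is 0-based [5,10), i.e. "GGGGG"
  expect_identical(upstream_context(plus, ref, 5)$upstream, "GGGGG")
  expect_identical(upstream_context(plus, ref, 7)$upstream, "TTGGGGG")
  expect_identical(upstream_context(transform(plus, start = 3L), ref,
                                    5)$upstream, "TTT")
  expect_identical(upstream_context(transform(plus, start = 0L), ref,
                                    5)$upstream, "")
  minus <- transform(plus, strand = "-", start = 10L, end = 45L)
  expect_identical(upstream_context(minus, ref, 5)$upstream,
                   revcomp(substr(ref[[1]], 46, 50)))
  expect_error(upstream_context(transform(plus, ref = "gX"), ref, 5),
               "missing contigs")
})

test_that("strand_invasion_report recovers injected truth", {
  # all-invasion, zero injected mutations would need mutate_k bypass; use
  # the generator's 0-3 load: every read must still be flagged
  sim <- toy_simulation(n_cells = 4, depth = 25, n_genes = 80,
                        invasion_rate = 1)
  rep <- strand_invasion_report(sim$tags, sim$tx, method_config("pb10x"))
  expect_identical(rep$n_dedup_reads, 100L)
  expect_equal(rep$percent_flagged, 100)
  expect_identical(sum(rep$mismatch_histogram), rep$n_flagged)

  # invasion_rate = 0: false-positive floor near 0 (reported, not 0-asserted)
  clean <- toy_simulation(n_cells = 4, depth = 50, seed = 3)
  rep0 <- strand_invasion_report(clean$tags, clean$tx,
                                 method_config("pb10x"))
  expect_lt(rep0$percent_flagged, 2)
  expect_error(strand_invasion_report(sim$tags[0, ], sim$tx),
               "no records")
})
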