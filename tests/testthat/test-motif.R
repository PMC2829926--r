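test_that("log-ratio transform follows the stated pseudo-count formulas", {
  # uniform column: all frequencies (1+1)/(4+4) = 0.25 -> scores 0
  w0 <- weight_matrix(matrix(c(1, 1, 1, 1), 4, 1), "uniform")
  expect_equal(unname(w0$logratio[, 1]), rep(0, 4))
  expect_equal(w0$min_score, 0)
  expect_equal(w0$max_score, 0)
  expect_equal(w0$threshold, 0)
  # single column (4,0,0,0): A -> log2(2.5), others -> -1
  w1 <- weight_matrix(matrix(c(4, 0, 0, 0), 4, 1), "pointy")
  expect_equal(unname(w1$logratio["A", 1]), log2(2.5))
  expect_equal(unname(w1$logratio[c("C", "G", "T"), 1]), rep(-1, 3))
  expect_equal(w1$threshold, -1 + 0.8 * (log2(2.5) + 1))
})

test_that("JASPAR parsing accepts both dialects and rejects malformed input", {
  td <- withr::local_tempdir()
  f1 <- file.path(td, "m1.pfm")
  writeLines(c(">M1 test", "A [ 4 0 ]", "C [ 0 4 ]", "G [ 0 0 ]",
               "T [ 0 0 ]"), f1)
  w <- load_pfm(f1)
  expect_identical(w$motif_id, "M1")
  expect_equal(unname(w$counts[1, ]), c(4, 0))
  f2 <- file.path(td, "m2.pfm")
  writeLines(c("4 0", "0 4", "0 0", "0 0"), f2)
  expect_equal(load_pfm(f2)$counts, load_pfm(f1)$counts,
               ignore_attr = TRUE)
  writeLines(character(0), file.path(td, "bad0.pfm"))
  expect_error(load_pfm(file.path(td, "bad0.pfm")), "empty")
  writeLines(c("1 2", "3 4", "5 6"), file.path(td, "bad3.pfm"))
  expect_error(load_pfm(file.path(td, "bad3.pfm")), "4 count rows")
  writeLines(c("1 2", "3 4 5", "5 6", "1 1"), file.path(td, "ragged.pfm"))
  expect_error(load_pfm(file.path(td, "ragged.pfm")), "ragged")
  writeLines(c("1 2", "3 x", "5 6", "1 1"), file.path(td, "junk.pfm"))
  expect_error(load_pfm(file.path(td, "junk.pfm")), "non-numeric")
})

test_that("scanner equals the exhaustive-window oracle on random inputs", {
  set.seed(99)
  for (i in 1:150) {
    wm <- random_pfm(sample(2:6, 1))
    sq <- random_dna(sample(3:100, 1), allow_n = TRUE)
    mine <- scan_motif(sq, wm)
    orc <- oracle_scan(sq, wm)
    expect_identical(nrow(mine), nrow(orc))
    if (nrow(orc)) {
      expect_identical(mine$position, orc$position)
      expect_identical(mine$strand, orc$strand)
      expect_equal(mine$score, orc$score, tolerance = 1e-10)
    }
  }
})

test_that("scanner edge behaviour: short sequences, Ns, strand symmetry", {
  wm <- panel_motifs()$MSYN03_Ebox
  expect_identical(nrow(scan_motif("ACGT", wm)), 0L)     # shorter than L
  expect_error(scan_motif("ACGTXX", wm), "outside")
  # strand symmetry: a sequence and its reverse complement give equal totals
  set.seed(5)
  for (i in 1:20) {
    sq <- random_dna(60)
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(sq, "")[[1]]), collapse = ""))
    expect_identical(nrow(scan_motif(sq, wm)), nrow(scan_motif(rc, wm)))
  }
})

test_that("raising threshold_fraction never increases hit counts", {
  set.seed(21)
  seqs <- vapply(1:15, function(i) random_dna(120), "")
  names(seqs) <- paste0("p", 1:15)
  counts <- panel_motifs()$MSYN03_Ebox$counts
  hits <- vapply(c(0.5, 0.7, 0.8, 0.9, 1.0), function(fr)
    profile_set(seqs, weight_matrix(counts, "m", threshold_fraction = fr)
                )$total_hits, 0L)
  expect_true(all(diff(hits) <= 0))
})

test_that("hit profiles register sequences, hits and scanned bp correctly", {
  wm3 <- weight_matrix(matrix(c(20, 0, 0, 0,
                                20, 0, 0, 0,
                                20, 0, 0, 0), 4, 3), "AAA",
                       threshold_fraction = 1)
  # one 10-bp N-free sequence, L = 3 -> 2 * 8 = 16 scanned window starts
  hp <- profile_set(c(s1 = "ACGTACGTAC"), wm3)
  expect_identical(hp$total_scanned_bp, 16)
  expect_identical(hp$total_hits, 0L)
  # AAA-motif at full threshold: hits = forward AAA runs + reverse TTT
  hp2 <- profile_set(c(s1 = "AAAACGTTTT"), wm3)
  expect_identical(hp2$total_hits, 4L)   # 2 forward AAA + 2 reverse (TTT)
  expect_identical(hp2$n_sequences_with_hit, 1L)
  # all sequences shorter than L -> zero everything
  hp3 <- profile_set(c(a = "AC", b = "GT"), wm3)
  expect_identical(hp3$total_scanned_bp, 0)
  # duplicating sequences doubles tallies
  seqs <- c(x = "AAAACGTTTT", y = "ACGTACGTAC")
  h1 <- profile_set(seqs, wm3)
  h2 <- profile_set(c(seqs, seqs), wm3)
  expect_identical(h2$total_hits, 2L * h1$total_hits)
  expect_identical(h2$total_scanned_bp, 2 * h1$total_scanned_bp)
  # N windows drop out of both numerator and denominator
  hpN <- profile_set(c(s1 = "AAANAAA"), wm3)
  # valid windows per strand: positions 1..5 minus those covering N (1,2,3 hit N at pos4): windows 1,2,3 contain N? windows start 1..5 length 3:
  # [1-3],[2-4],[3-5],[4-6],[5-7]; N at 4 -> windows 2,3,4 invalid -> 2 valid
  expect_identical(hpN$total_scanned_bp, 4)
  expect_identical(hpN$total_hits, 2L)   # forward AAA at windows 1 and 5
})

test_that("Fisher wrapper equals the hypergeometric enumeration oracle", {
  mkhp <- function(with_hit, n) structure(
    list(motif_id = "m", n_sequences = n, n_sequences_with_hit = with_hit,
         total_hits = with_hit, total_scanned_bp = n * 100),
    class = "HitProfile")
  # symmetric table -> p = 1
  expect_equal(fisher_sequence_test(mkhp(1, 2), mkhp(1, 2))$p_value, 1)
  # equal rates -> p = 1
  expect_equal(fisher_sequence_test(mkhp(5, 10), mkhp(50, 100))$p_value, 1)
  # the worked 2x2 example against enumeration
  p <- fisher_sequence_test(mkhp(8, 10), mkhp(20, 100))$p_value
  expect_equal(p, oracle_fisher_two_sided(8, 2, 20, 80), tolerance = 1e-12)
  # random tables
  set.seed(3)
  for (i in 1:50) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    got <- fisher_sequence_test(mkhp(a, a + b), mkhp(c_, c_ + d))$p_value
    expect_equal(got, oracle_fisher_two_sided(a, b, c_, d), tolerance = 1e-10)
  }
  # Haldane-corrected odds ratio when a cell is empty
  res <- fisher_sequence_test(mkhp(0, 5), mkhp(3, 10))
  expect_equal(res$odds_ratio, (0.5 * 7.5) / (5.5 * 3.5))
  expect_error(fisher_sequence_test(mkhp(0, 0), mkhp(1, 2)), ">= 1")
})

test_that("Z-score follows the stated binomial formula", {
  hp <- function(hits, bp) structure(
    list(motif_id = "m", n_sequences = 10, n_sequences_with_hit = 1,
         total_hits = hits, total_scanned_bp = bp), class = "HitProfile")
  # hand evaluation: fg 30 hits / 1000 bp, bg rate 0.01
  z <- zscore_bp_test(hp(30, 1000), hp(100, 10000))
  expect_equal(z, (30 - 10) / sqrt(10 * 0.99), tolerance = 1e-12)
  # equal rates -> 0
  expect_equal(zscore_bp_test(hp(10, 1000), hp(100, 10000)), 0)
  # sqrt(n) scaling at fixed rates
  z1 <- zscore_bp_test(hp(30, 1000), hp(100, 10000))
  z2 <- zscore_bp_test(hp(15, 500), hp(100, 10000))
  expect_equal(z2, z1 / sqrt(2), tolerance = 1e-12)
  # degenerate background rate
  expect_warning(zn <- zscore_bp_test(hp(5, 100), hp(0, 100)), "undefined")
  expect_true(is.na(zn))
})

test_that("heatmap matrix is canonical and order-invariant", {
  et <- function(ids, z) structure(
    data.frame(motif_id = ids, z_score = z),
    class = c("EnrichmentTable", "data.frame"))
  res <- list(setB = et(c("m2", "m1"), c(2, -1)),
              setA = et(c("m1", "m2"), c(0.5, 3)))
  mat <- enrichment_heatmap(res)
  expect_identical(rownames(mat), c("m1", "m2"))
  expect_identical(colnames(mat), c("setA", "setB"))
  expect_equal(mat["m2", "setB"], 2)
  # permuting input order leaves the matrix unchanged
  expect_identical(enrichment_heatmap(rev(res)), mat)
  # single motif, single set -> 1x1 equal to that z
  one <- enrichment_heatmap(list(s = et("m", 1.23)))
  expect_equal(unname(one[1, 1]), 1.23)
  # written TSV round-trips
  td <- withr::local_tempdir()
  enrichment_heatmap(res, file.path(td, "h.tsv"))
  back <- read.delim(file.path(td, "h.tsv"), check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), mat, ignore_attr = TRUE)
})

test_that("FASTA promoter I/O truncates to the proximal window", {
  td <- withr::local_tempdir()
  seqs <- c(p1 = paste(rep("ACGT", 10), collapse = ""),
            p2 = "GGGTTTAAACCC")
  write_promoters(seqs, file.path(td, "p.fa"))
  back <- read_promoters(file.path(td, "p.fa"), window = 12)
  expect_identical(unname(nchar(back)), c(12L, 12L))
  # right-truncation keeps the 3' end
  expect_identical(unname(back["p1"]), unname(substr(seqs["p1"], 29, 40)))
  expect_identical(unname(back["p2"]), unname(seqs["p2"]))
})
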