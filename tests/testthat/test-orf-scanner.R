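test_that("uATG scanning reports exactly the upstream ATG triplets", {
  expect_identical(scan_uatgs(utr_record("G", "T", "CCATGCC"))$pos_satg, -5L)
  expect_identical(nrow(scan_uatgs(utr_record("G", "T", "CCCCCCC"))), 0L)
  # triplet straddling the sATG is excluded
  rec <- utr_record("G", "T", "CCCCATG", utr_length = 6,
                    cds_prefix_length = 1)
  expect_identical(nrow(scan_uatgs(rec)), 0L)
  # planted positions recovered exactly
  sim <- sim_utr(utr_length = 100L,
                 uatgs = data.frame(pos = c(-80L, -33L), context = c(2L, 1L)),
                 seed = 5)
  expect_identical(scan_uatgs(sim$record)$pos_satg, c(-80L, -33L))
  # N never matches
  expect_identical(nrow(scan_uatgs(utr_record("G", "T", "CCNTGATNCC"))), 0L)
})

test_that("context grading follows the two key positions", {
  expect_identical(classify_context("GCCACCATGG"), 4L)
  expect_identical(classify_context("GCCGCCATGG"), 4L)
  expect_identical(classify_context("AAAGAAATGG"), 3L)
  expect_identical(classify_context("AAACAAATGG"), 2L)
  expect_identical(classify_context("AAAAAAATGC"), 2L)
  expect_identical(classify_context("AAATAAATGC"), 1L)
  expect_identical(classify_context("NNNNNNATGN"), 1L)
  expect_error(classify_context("AAAAAAAAAA"), "no ATG")
  # truncated 5' end: graded on +4 alone
  expect_identical(classify_context("ATGG", atg_at = 1L), 2L)
  expect_identical(classify_context("ATGC", atg_at = 1L), 1L)
})

test_that("TIS score binning uses inclusive middle bounds", {
  expect_identical(bin_tis(0.05), 1L)
  expect_identical(bin_tis(0.1), 2L)
  expect_identical(bin_tis(0.5), 2L)
  expect_identical(bin_tis(0.51), 3L)
  expect_error(bin_tis(1.2), "0, 1")
  expect_error(bin_tis(-0.1), "0, 1")
})

test_that("uORF calls match the printed conventions", {
  # 3 codons incl. stop
  rec <- utr_record("G", "T", paste0("ATGAAATAA", strrep("C", 20)))
  u <- find_uorfs(rec, min_len_nt = 9)
  expect_identical(u$start, -29L)
  expect_identical(u$end, -21L)
  expect_identical(u$length_nt, 9L)
  expect_false(u$overlaps_morf)
  # no in-frame stop before the sATG: open-ended, overlapping the mORF,
  # lower-bound length = complete upstream codons
  rec2 <- utr_record("G", "T", paste0(strrep("C", 5), "ATG", strrep("C", 81)))
  u2 <- find_uorfs(rec2)
  expect_true(u2$open_ended)
  expect_true(u2$overlaps_morf)
  expect_identical(u2$length_nt, 84L)
  expect_identical(u2$start, -84L)
  # stop inside a provided CDS prefix closes the uORF past the sATG
  rec3 <- utr_record("G", "T", paste0("CCCCATGCC", "ATGCTAACCC"),
                     utr_length = 9, cds_prefix_length = 10)
  u3 <- find_uorfs(rec3, min_len_nt = 6)
  expect_identical(u3$end, 7L)
  expect_false(u3$open_ended)
  expect_true(u3$overlaps_morf)
  expect_identical(u3$length_nt, interval_length(-5L, 7L))
})

test_that("uORF scan agrees with a brute-force oracle on random sequences", {
  set.seed(11)
  for (k in 1:40) {
    L <- sample(30:200, 1)
    prefix <- sample(c(0L, 12L), 1)
    seq <- if (prefix > 0) paste0(random_seq(L), "ATG", random_seq(prefix - 3))
           else random_seq(L)
    rec <- utr_record("G", "T", seq, utr_length = L,
                      cds_prefix_length = prefix)
    got <- find_uorfs(rec, min_len_nt = 9)
    exp <- oracle_uorfs(rec$sequence, L, 9)
    got_i <- sort(vapply(seq_len(nrow(got)), function(r) {
      unname(got$start[r] + L + 1L)
    }, numeric(1)))
    expect_identical(as.integer(got_i), sort(exp$i))
    closed <- got[!got$open_ended, , drop = FALSE]
    if (nrow(closed) > 0) {
      expect_true(all(closed$length_nt %% 3 == 0))
      expect_identical(closed$length_nt,
                       interval_length(closed$start, closed$end))
    }
  }
})

test_that("every uORF starts at a reported uATG and flags are consistent", {
  set.seed(23)
  for (k in 1:10) {
    rec <- utr_record("G", "T", random_seq(150))
    res <- scan_utr(rec, min_len_nt = 9)
    expect_true(all(res$uorfs$start %in% res$uatgs$pos_satg))
    expect_identical(res$uatgs$starts_uorf,
                     res$uatgs$pos_satg %in% res$uorfs$start)
  }
})
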