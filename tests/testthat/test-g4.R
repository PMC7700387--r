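test_that("pattern detector finds and merges canonical quadruplexes", {
  h <- pattern_g4("GGGAGGGAGGGAGGG")
  expect_identical(nrow(h), 1L)
  expect_identical(c(h$start, h$end), c(1L, 15L))
  expect_identical(nrow(pattern_g4("ATATATAT")), 0L)
  # overlapping matches merge into one maximal region
  h2 <- pattern_g4("GGGAGGGAGGGAGGGAGGG")
  expect_identical(nrow(h2), 1L)
  expect_identical(c(h2$start, h2$end), c(1L, 19L))
  # loop length bounds respected
  expect_identical(nrow(pattern_g4("GGGAAAAAAAAGGGAGGGAGGG")), 0L)
})

test_that("G-score rewards tetrads and even loops", {
  even <- qgrs_scan("GGGAAGGGAAGGGAAGGG")
  uneven <- qgrs_scan("GGGAGGGAAAAGGGAGGG")
  expect_identical(nrow(even), 1L)
  expect_gt(even$score, uneven$score)
  # one more tetrad at equal span and loops scores +10
  x2 <- qgrs_scan("GGAAGGAAGGAAGG")
  x3 <- qgrs_scan("GGGAAGGGAAGGGAAGGG")
  delta_len <- (nchar("GGGAAGGGAAGGGAAGGG") - nchar("GGAAGGAAGGAAGG"))
  expect_equal(x3$score - x2$score, 10 - delta_len)
  expect_identical(nrow(qgrs_scan("GGGAAGGGAAGGG")), 0L)
})

test_that("window scorer matches hand-computed values and bounds", {
  expect_equal(g4hunter(strrep("G", 25))$window_means, 4)
  g <- g4hunter("GGTTGG")
  expect_identical(g$base_scores, c(2L, 2L, 0L, 0L, 2L, 2L))
  expect_equal(g$window_means, mean(c(2, 2, 0, 0, 2, 2)))
  expect_equal(g4hunter(strrep("ACGT", 6))$window_means, 0)
  set.seed(3)
  for (k in 1:10) {
    s <- random_seq(60)
    sc <- g4hunter(s)$base_scores
    expect_true(all(abs(sc) <= 4))
    # reverse complement negates and reverses the per-base score vector
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                collapse = "")
    expect_identical(g4hunter(rc)$base_scores, -rev(sc))
  }
})

test_that("detectors are position-covariant under prefixing", {
  s <- "TTGGGAGGGTGGGAGGGTTT"
  for (k in c(3L, 10L)) {
    pre <- paste0(strrep("T", k), s)
    p0 <- pattern_g4(s); p1 <- pattern_g4(pre)
    expect_identical(p1$start, p0$start + k)
    expect_identical(p1$end, p0$end + k)
    q0 <- qgrs_scan(s); q1 <- qgrs_scan(pre)
    expect_identical(q1$start, q0$start + k)
  }
})

test_that("consensus is the pairwise intersection with fallback order", {
  full <- data.frame(start = 10L, end = 40L, score = 1)
  expect_identical(consensus_g4(full, full, full)$n_supporting, 3L)
  a <- data.frame(start = 1L, end = 31L)
  b <- data.frame(start = 16L, end = 41L)
  out <- consensus_g4(a, b, data.frame(start = integer(0), end = integer(0)))
  expect_identical(c(out$start, out$end), c(16L, 31L))
  expect_identical(out$detectors, "pattern+g4hunter")
  # no pattern/g4hunter overlap -> fall back to pattern/qgrs
  out2 <- consensus_g4(a, data.frame(start = 90L, end = 120L), b)
  expect_identical(out2$detectors, "pattern+qgrs")
  # disjoint everywhere -> empty
  expect_identical(nrow(consensus_g4(a, data.frame(start = 90L, end = 120L),
                                     data.frame(start = 50L, end = 70L))), 0L)
  # consensus intervals lie inside each supporting hit
  expect_true(out$start >= max(a$start, b$start))
  expect_true(out$end <= min(a$end, b$end))
})

test_that("planted canonical motifs reach three-detector consensus", {
  sim <- sim_utr(utr_length = 200L, g4_sites = c(-150L, -60L), seed = 77)
  g <- scan_g4(sim$record)
  expect_identical(nrow(g$consensus), 2L)
  for (k in 1:2) {
    expect_gte(g$consensus$start[k], sim$truth$g4$start[k])
    expect_lte(g$consensus$end[k], sim$truth$g4$end[k])
    expect_gte(interval_length(g$consensus$start[k], g$consensus$end[k]), 12L)
    expect_gte(g$consensus$n_supporting[k], 2L)
  }
})
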