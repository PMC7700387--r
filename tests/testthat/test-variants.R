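abca10_features <- function() abca_gene_features("ABCA10")

test_that("uORF-start disruption, containment and background classes", {
  f <- abca10_features()
  # A>G at the first base of the uORF starting at -482 kills its ATG
  v <- classify_variant(-482, "A", "G", f)
  expect_true("uorf_start_disruption" %in% v$classes)
  expect_false("within_uorf" %in% v$classes)
  # -438 lies in the most conserved region only
  v2 <- classify_variant(-438, "C", "A", f)
  expect_identical(setdiff(v2$classes, "within_conserved_region"),
                   character(0))
  # -762 hits nothing
  expect_identical(classify_variant(-762, "C", "A", f)$classes, "none")
  # open-ended uORFs extend to the base before the sATG
  fa1 <- abca_gene_features("ABCA1")
  expect_true("within_uorf" %in% classify_variant(-18, "G", "C", fa1)$classes)
  expect_false("within_uorf" %in%
                 classify_variant(-279, "C", "G", fa1)$classes)
})

test_that("coding effects are read in the uORF frame from the sequence", {
  sim <- sim_utr(utr_length = 120L,
                 uorfs = data.frame(start = -100L, length = 45L),
                 seed = 41)
  feats <- list(uorfs = sim$truth$uorfs)
  seqc <- sim$record$sequence
  # wobble substitution that preserves the amino acid
  v <- sim_variants(sim$record, sim$truth, classes = "synonymous", seed = 2)
  res <- classify_variant(v$pos, v$ref, v$alt, feats, sequence = seqc,
                          utr_length = 120L)
  expect_identical(res$coding_effect, "synonymous")
  # destroying the stop codon is a stop_loss
  stop_pos <- sim$truth$uorfs$end[1] - 2L
  res2 <- classify_variant(stop_pos, "T", "C", feats, sequence = seqc,
                           utr_length = 120L)
  expect_identical(res2$coding_effect, "stop_loss")
  # non-triplet indel inside the uORF is a frameshift
  res3 <- classify_variant(-90L, substr(seqc, 31, 31),
                           paste0(substr(seqc, 31, 31), "AA"), feats,
                           sequence = seqc, utr_length = 120L)
  expect_identical(res3$coding_effect, "frameshift")
  # reference mismatch is reported with its position
  wrong <- setdiff(c("A", "C", "G", "T"), substr(seqc, 31, 31))[1]
  expect_error(classify_variant(-90L, wrong, "A", feats, sequence = seqc,
                                utr_length = 120L), "-90")
})

test_that("classification is pure and ref/alt swaps restore the class", {
  f <- abca10_features()
  for (k in 1:5) {
    v1 <- classify_variant(-450, "A", "G", f)
    expect_identical(v1, classify_variant(-450, "A", "G", f))
  }
  fwd <- classify_variant(-482, "A", "G", f)
  # on the mutated allele the same swap back disrupts nothing: G->A restores
  # the ATG, so the position is again inside uORF3
  back <- classify_variant(-482, "G", "A", f)
  expect_false("uorf_start_disruption" %in% back$classes)
  expect_true("within_uorf" %in% back$classes)
  expect_true("uorf_start_disruption" %in% fwd$classes)
})

test_that("class tallies avoid double counting", {
  vs <- data.frame(pos = c(-482L, -460L, -450L, -762L),
                   ref = c("A", "C", "C", "C"),
                   alt = c("G", "A", "A", "A"))
  f <- abca10_features()
  cls <- count_by_class(classify_variants(vs, f))
  expect_identical(unname(cls["uorf_start_disruption"]), 1L)
  expect_identical(unname(cls["within_uorf"]), 2L)
  expect_identical(unname(cls["none"]), 1L)
  # a variant inside two overlapping uORFs still counts once
  fo <- list(uorfs = data.frame(start = c(-279L, -265L), end = c(-247L, -95L),
                                open_ended = c(FALSE, FALSE)))
  one <- classify_variants(data.frame(pos = -260L, ref = "C", alt = "A"), fo)
  expect_identical(unname(count_by_class(one)["within_uorf"]), 1L)
  # empty variant set tallies all zero
  none <- classify_variants(vs[0, , drop = FALSE], f)
  expect_true(all(count_by_class(none) == 0L))
})

test_that("planted variants of every class are recovered exactly", {
  for (seed in c(3, 9, 27)) {
    layout <- sim_layout(seed = seed, category = 3L)
    sim <- layout$sim
    v <- sim_variants(sim$record, sim$truth, seed = seed + 1)
    feats <- list(uorfs = sim$truth$uorfs,
                  uatgs = data.frame(pos = sim$truth$uatgs$pos),
                  rg4 = sim$truth$g4)
    cv <- classify_variants(v, feats, sequence = sim$record$sequence,
                            utr_length = sim$record$utr_length)
    expect_identical(
      ifelse(cv$true_class == "start_disruption", "uorf_start_disruption",
             ifelse(cv$true_class == "none", "none", "within_uorf")),
      vapply(strsplit(cv$classes, "+", fixed = TRUE), `[`, character(1), 1))
    expect_identical(cv$coding_effect[cv$true_class == "synonymous"],
                     "synonymous")
    expect_identical(cv$coding_effect[cv$true_class == "nonsynonymous"],
                     "nonsynonymous")
    expect_identical(cv$coding_effect[cv$true_class == "frameshift"],
                     "frameshift")
  }
})
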