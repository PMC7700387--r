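random_msa <- function(n_rows = 11, n_cols = 60) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_rows * n_cols, replace = TRUE),
              nrow = n_rows)
  rownames(m) <- c("human", paste0("sp", seq_len(n_rows - 1)))
  m
}

test_that("column identity and occupancy match hand computation", {
  m <- matrix("A", nrow = 11, ncol = 5)
  rownames(m) <- c("human", paste0("sp", 1:10))
  p <- profile_alignment(m, "human")
  expect_true(all(p$identity == 100))
  expect_true(all(p$occupancy == 100))
  # 8 A, 2 G, 1 gap in an 11-row column
  m[, 3] <- c(rep("A", 8), "G", "G", "-")
  p <- profile_alignment(m, "human")
  expect_equal(p$occupancy[3], 100 * 10 / 11, tolerance = 1e-12)
  expect_equal(p$identity[3], 80)
  # human-gap column absent from the coordinate map
  m[1, 3] <- "-"
  p <- profile_alignment(m, "human")
  expect_true(is.na(p$column_to_human[3]))
  expect_identical(p$column_to_human[c(1, 2, 4, 5)], c(-4L, -3L, -2L, -1L))
  expect_error(profile_alignment(m, "mouse"), "not found")
})

test_that("conserved subregions are the planted runs and nothing else", {
  set.seed(19)
  m <- random_msa()
  m[, 10:20] <- matrix(rep(m[1, 10:20], each = nrow(m)), nrow = nrow(m))
  p <- profile_alignment(m, "human")
  reg <- find_conserved_subregions(p)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$start, p$column_to_human[10])
  expect_identical(reg$end, p$column_to_human[20])
  expect_equal(reg$mean_identity, 100)
  # all-random alignments yield nothing at the default cut-offs
  for (s in 1:5) {
    set.seed(100 + s)
    expect_identical(nrow(find_conserved_subregions(
      profile_alignment(random_msa(), "human"))), 0L)
  }
  # degenerate cut-offs span everything
  all_reg <- find_conserved_subregions(p, identity_cutoff = 0,
                                       occupancy_cutoff = 0, min_run = 1)
  expect_identical(nrow(all_reg), 1L)
  expect_identical(all_reg$start, -ncol(m))
  expect_identical(all_reg$end, -1L)
})

test_that("subregions do not overlap and ignore flanking all-gap padding", {
  set.seed(31)
  m <- random_msa()
  m[, 10:20] <- matrix(rep(m[1, 10:20], each = nrow(m)), nrow = nrow(m))
  m[, 35:45] <- matrix(rep(m[1, 35:45], each = nrow(m)), nrow = nrow(m))
  reg <- find_conserved_subregions(profile_alignment(m, "human"))
  expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
  pad <- matrix("-", nrow(m), 4)
  padded <- cbind(pad, m, pad)
  rownames(padded) <- rownames(m)
  reg2 <- find_conserved_subregions(profile_alignment(padded, "human"))
  expect_identical(reg, reg2)
})

test_that("uATG conservation categories follow the nested group scale", {
  layout <- sim_layout(seed = 101, category = 5L)
  msa <- layout$msa
  expect_identical(uatg_conservation_category(msa$msa, "human", -280,
                                              msa$groups), 5L)
  # destroying groups one by one never raises the category (monotone)
  m <- msa$msa
  idx <- 300 + (-280) + 1 + 0:2
  prev <- 5L
  for (g in c("fishes", "sauropsids", "other_placental", "rodents",
              "primates")) {
    rows <- names(msa$groups)[msa$groups == g]
    m[rows, idx[2]] <- "C"
    cat_now <- suppressWarnings(
      uatg_conservation_category(m, "human", -280, msa$groups))
    expect_lte(cat_now, prev)
    prev <- cat_now
  }
  expect_identical(prev, 0L)
  # non-nested pattern: primates + fishes only -> category 1 with warning
  m2 <- msa$msa
  for (g in c("rodents", "other_placental", "sauropsids")) {
    rows <- names(msa$groups)[msa$groups == g]
    m2[rows, idx[2]] <- "C"
  }
  expect_warning(cat2 <- uatg_conservation_category(m2, "human", -280,
                                                    msa$groups),
                 "non-monotone")
  expect_identical(cat2, 1L)
  # human-gap columns are an error
  m3 <- msa$msa
  m3["human", idx[1]] <- "-"
  expect_error(uatg_conservation_category(m3, "human", -280, msa$groups))
})

test_that("simulated ortholog sets recover every target category", {
  for (target in 0:5) {
    layout <- sim_layout(seed = 200 + target, category = target)
    msa <- layout$msa
    for (p in c(-280, -150)) {
      expect_identical(
        uatg_conservation_category(msa$msa, "human", p, msa$groups),
        target)
    }
  }
})
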