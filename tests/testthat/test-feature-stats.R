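test_that("feature table rows satisfy the element-count identity", {
  tab <- build_feature_table(gene_id = c("g1", "g2", "g3"),
                             utr_length = c(910L, 26L, 313L),
                             n_uatg = c(14L, 0L, 1L), n_uorf = c(6L, 0L, 1L),
                             n_intron = c(3L, 0L, 1L), n_rg4 = c(0L, 0L, 1L),
                             n_stem_loops = c(5L, 0L, 6L))
  expect_identical(tab$n_all_elements, c(22L, 0L, 9L))
  expect_error(build_feature_table("g", 10L, NA_integer_, 0L, 0L, 0L, 0L),
               "missing")
})

test_that("descriptive statistics match a naive reference on random data", {
  set.seed(57)
  for (k in 1:30) {
    x <- sample(0:8, sample(2:25, 1), replace = TRUE)
    d <- describe_values(x)
    expect_identical(d$n, length(x))
    expect_identical(d$min, min(x))
    expect_identical(d$max, max(x))
    expect_identical(d$sum, sum(x))
    expect_equal(d$mean, sum(x) / length(x))
    expect_equal(d$variance, sum((x - mean(x))^2) / (length(x) - 1))
    sx <- sort(x)
    n <- length(x)
    expect_equal(d$median, if (n %% 2 == 1) sx[(n + 1) / 2]
                 else (sx[n / 2] + sx[n / 2 + 1]) / 2)
    tab <- table(x)
    if (max(tab) > 1) {
      best <- as.numeric(names(tab)[tab == max(tab)])
      expect_identical(as.numeric(d$mode), min(best))
    } else {
      expect_true(is.na(d$mode))
    }
  }
  d1 <- describe_values(5)
  expect_identical(c(d1$min, d1$max, d1$mean, d1$median, d1$mode),
                   rep(5, 5))
  expect_true(is.na(d1$variance))
  expect_error(describe_values(numeric(0)))
})

test_that("display rounding goes half away from zero", {
  expect_identical(round_half_away(c(211.5, 7207.5, 0.5, -0.5, 1.49)),
                   c(212, 7208, 1, -1, 1))
  expect_identical(round_half_away(2.345, 2), 2.35)
})

test_that("rank correlations match naive formulas and are monotone-invariant", {
  set.seed(71)
  for (k in 1:20) {
    n <- sample(5:15, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(cor_spearman(x, y), oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(cor_kendall(x, y), oracle_kendall_b(x, y), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(cor_spearman(exp(x), y), cor_spearman(x, y))
    expect_equal(cor_kendall(x, y^3 + 2), cor_kendall(x, y))
  }
  expect_equal(cor_spearman(1:5, c(2, 4, 5, 7, 11)), 1)
  expect_equal(cor_kendall(1:5, c(2, 4, 5, 7, 11)), 1)
  expect_equal(cor_spearman(1:5, 5:1), -1)
  expect_error(cor_spearman(rep(1, 5), 1:5), "constant")
})

test_that("t-based p-values follow the stated transform", {
  r <- 0.7586442  # bundled-table value for length vs uATG count, n = 12
  t <- r * sqrt(10 / (1 - r^2))
  expect_equal(cor_p_t(r, 12), 2 * pt(-abs(t), df = 10))
  expect_equal(cor_p_t(1, 12), 0)
})

test_that("permutation p is seeded, reproducible and converges to exact", {
  x <- c(3, 1, 4, 1, 5, 9)
  y <- c(2, 7, 1, 8, 2, 8)
  p1 <- permutation_p(x, y, "spearman", n_perm = 500, seed = 42)
  p2 <- permutation_p(x, y, "spearman", n_perm = 500, seed = 42)
  expect_identical(p1, p2)
  exact <- oracle_exact_perm_p(x, y, "spearman")
  p_big <- permutation_p(x, y, "spearman", n_perm = 20000, seed = 7)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(p_big - exact), 4 * se + 1e-4)
})

test_that("pairwise correlation tables carry both significance routes", {
  f <- abca_table("features")
  res <- correlate_features(f, pairs = cbind("utr_length", "n_uatg"),
                            n_perm = 999, seed = 3)
  expect_identical(res$n, 12L)
  # published regression values for this pair (0.004 / 0.006)
  expect_equal(round(res$p_t_spearman, 3), 0.004)
  expect_equal(round(res$p_z_kendall, 3), 0.006)
  expect_false(is.na(res$p_perm_spearman))
  expect_lt(res$p_perm_spearman, 0.05)
})
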