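# Independent brute-force oracles used across the suite.

msa_rows <- function(v) utr5scan:::msa_matrix(v)

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# enumerate the signed no-zero coordinate scale and count positions
oracle_interval_length <- function(start, end) {
  scale <- setdiff(seq(min(start, -1L), max(end, 1L)), 0L)
  sum(scale >= start & scale <= end)
}

# enumerate all uORFs by direct substring tests; returns a data.frame of
# sequence indices (end NA for unterminated reads)
oracle_uorfs <- function(seq, utr_length, min_len) {
  n <- nchar(seq)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(max(utr_length - 2L, 0L))) {
    if (substr(seq, i, i + 2L) != "ATG") next
    closed <- FALSE
    for (j in seq(i, n - 2L, by = 3L)) {
      if (substr(seq, j, j + 2L) %in% stops) {
        if (j + 2L - i + 1L >= min_len) {
          out[[length(out) + 1L]] <- data.frame(i = i, j = j + 2L)
        }
        closed <- TRUE
        break
      }
    }
    if (!closed) out[[length(out) + 1L]] <- data.frame(i = i, j = NA_integer_)
  }
  if (length(out) == 0) return(data.frame(i = integer(0), j = integer(0)))
  do.call(rbind, out)
}

# exhaustive maximum-pairing search by naive recursion (no DP table)
oracle_max_pairs <- function(seq, min_hairpin = 3L, allow_gu = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  ok <- function(a, b) {
    p <- paste0(chars[a], chars[b])
    p %in% c("AT", "TA", "GC", "CG") ||
      (allow_gu && p %in% c("GT", "TG"))
  }
  rec <- function(i, j) {
    if (i >= j || j - i <= min_hairpin) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_hairpin + 1L):j) {
      if (ok(i, k)) best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  rec(1L, length(chars))
}

pearson_hand <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

oracle_spearman <- function(x, y) pearson_hand(rank(x), rank(y))

oracle_kendall_b <- function(x, y) {
  n <- length(x)
  nc <- 0L; nd <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) nc <- nc + 1L else if (s < 0) nd <- nd + 1L
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(vapply(table(x), function(t) t * (t - 1) / 2, numeric(1)))
  n2 <- sum(vapply(table(y), function(t) t * (t - 1) / 2, numeric(1)))
  (nc - nd) / sqrt((n0 - n1) * (n0 - n2))
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_permutations(v[-i]), function(p) c(v[i], p))
  }))
}

# exact two-sided permutation p over all n! rearrangements
oracle_exact_perm_p <- function(x, y, method = "spearman") {
  obs <- abs(cor(x, y, method = method))
  vals <- vapply(all_permutations(y), function(py) {
    abs(cor(x, py, method = method))
  }, numeric(1))
  mean(vals >= obs - 1e-12)
}

# fixed synthetic feature layout used by the pipeline-recovery tests
sim_layout <- function(seed, category) {
  sim <- sim_utr(utr_length = 300L,
                 uatgs = data.frame(pos = c(-280L, -150L),
                                    context = c(4L, 1L)),
                 uorfs = data.frame(start = c(-120L, -60L),
                                    length = c(33L, NA),
                                    open = c(FALSE, TRUE)),
                 g4_sites = -250L,
                 hairpins = data.frame(pos = -190L, stem = 5L, loop = 4L),
                 seed = seed)
  msa <- sim_ortholog_msa(sim$record, uatg_pos = c(-280L, -150L),
                          target_categories = c(category, category),
                          seed = seed + 1L)
  list(sim = sim, msa = msa)
}
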