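#' Assemble the per-gene 5'UTR feature table
#'
#' One row per gene with the counts of each feature class and the total
#' element count. The total counts uATGs, introns, G-quadruplex regions
#' and stem loops; uORFs are excluded from the total because every uORF
#' already contributes its uATG (each row of the bundled reference table
#' obeys this identity).
#'
#' @param gene_id character vector.
#' @param utr_length,n_uatg,n_uorf,n_intron,n_rg4,n_stem_loops integer
#'   vectors (recycled against `gene_id`).
#' @param total_intron_length,satg_context,tissue_distribution,mode_expression
#'   optional per-gene columns.
#' @return data.frame with an additional `n_all_elements` column.
#' @export
build_feature_table <- function(gene_id, utr_length, n_uatg, n_uorf,
                                n_intron, n_rg4, n_stem_loops,
                                total_intron_length = NA_integer_,
                                satg_context = NA_integer_,
                                tissue_distribution = NA_integer_,
                                mode_expression = NA_integer_) {
  out <- data.frame(gene_id = gene_id, utr_length = utr_length,
                    n_uatg = n_uatg, n_uorf = n_uorf, n_intron = n_intron,
                    total_intron_length = total_intron_length,
                    n_rg4 = n_rg4, n_stem_loops = n_stem_loops,
                    satg_context = satg_context,
                    tissue_distribution = tissue_distribution,
                    mode_expression = mode_expression)
  counts <- out[, c("n_uatg", "n_intron", "n_rg4", "n_stem_loops")]
  if (any(is.na(counts)) || any(counts < 0)) {
    bad <- out$gene_id[!stats::complete.cases(counts) |
                         apply(counts, 1, function(r) any(r < 0, na.rm = TRUE))]
    stop("missing or negative feature counts for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out$n_all_elements <- out$n_uatg + out$n_intron + out$n_rg4 +
    out$n_stem_loops
  out
}

#' Descriptive statistics of a feature column
#'
#' Reports n, min, max, sum, mean, sample variance (denominator n - 1,
#' `NA` for a single value), median (midpoint average for even n) and
#' mode. The mode is the most frequent value, ties broken by the smallest
#' value; when no value repeats the mode is `NA` ("not applicable"). Raw
#' values are kept; use [format_descriptives()] for display rounding.
#'
#' @param x numeric vector (no NAs).
#' @return list of class `descriptive_stats`.
#' @examples
#' describe_values(c(4, 1, 1, 0, 14, 2, 4, 0, 3, 6, 1, 1))
#' @export
describe_values <- function(x) {
  if (length(x) == 0 || any(is.na(x))) {
    stop("describe_values() needs at least one non-missing value",
         call. = FALSE)
  }
  ux <- sort(unique(x))
  freq <- tabulate(match(x, ux))
  mode <- if (max(freq) <= 1L && length(x) > 1L) NA_real_
          else ux[which.max(freq)]
  structure(list(n = length(x), min = min(x), max = max(x), sum = sum(x),
                 mean = mean(x),
                 variance = if (length(x) < 2) NA_real_ else var(x),
                 median = median(x), mode = mode),
            class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  v <- unlist(x)
  cat(paste(format(names(v), width = 9), signif(v, 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used for summary tables (so 211.5 prints as 212 and
#' -0.5 as -1), unlike R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format descriptive statistics for table display
#'
#' @param stats a [describe_values()] result.
#' @param digits decimal places (default 0, integers).
#' @return named numeric vector rounded half away from zero.
#' @export
format_descriptives <- function(stats, digits = 0) {
  v <- unlist(unclass(stats))
  out <- round_half_away(v, digits)
  out["n"] <- v["n"]
  out
}

#' Nonparametric correlation with t-based and permutation significance
#'
#' `cor_spearman()` is the Pearson correlation of midranks;
#' `cor_kendall()` is tau-b (tie-corrected). `cor_p_t()` converts a
#' correlation to a two-tailed p-value through
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' `permutation_p()` is a seeded Monte-Carlo permutation test with
#' estimator `(1 + #{|stat_perm| >= |stat_obs|}) / (1 + n_perm)`.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param r a correlation coefficient.
#' @param n number of paired observations.
#' @param statistic which coefficient to permute.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed making the test reproducible.
#' @return numeric scalar.
#' @export
cor_spearman <- function(x, y) {
  check_cor_input(x, y)
  cor(x, y, method = "spearman")
}

#' @rdname cor_spearman
#' @export
cor_kendall <- function(x, y) {
  check_cor_input(x, y)
  cor(x, y, method = "kendall")
}

#' @rdname cor_spearman
#' @export
cor_p_t <- function(r, n) {
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' @rdname cor_spearman
#' @export
tau_p_normal <- function(r, n) {
  if (n < 3) stop("need n >= 3", call. = FALSE)
  z <- 3 * r * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' @rdname cor_spearman
#' @export
permutation_p <- function(x, y, statistic = c("spearman", "kendall",
                                              "pearson"),
                          n_perm = 9999L, seed = 1L) {
  statistic <- match.arg(statistic)
  check_cor_input(x, y)
  method <- if (statistic == "pearson") "pearson" else statistic
  obs <- abs(cor(x, y, method = method))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- 0L
  n <- length(y)
  for (k in seq_len(n_perm)) {
    stat <- abs(cor(x, y[sample.int(n)], method = method))
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (any(is.na(x)) || any(is.na(y))) stop("missing values in input",
                                           call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  invisible(TRUE)
}

#' Correlate feature-table columns pairwise
#'
#' Runs Spearman and Kendall correlations (with t-based p-values and,
#' optionally, permutation p-values) for each requested column pair of a
#' feature table. Rows with missing values in a pair are dropped for that
#' pair. No multiple-testing correction is applied by default; set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted columns.
#'
#' @param features data.frame of per-gene features.
#' @param pairs two-column character matrix/data.frame of column names;
#'   defaults to all unordered pairs of `columns`.
#' @param columns columns to cross when `pairs` is NULL.
#' @param n_perm permutations per pair (0 skips permutation tests).
#' @param seed base seed for the permutation tests.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per pair.
#' @export
correlate_features <- function(features, pairs = NULL, columns = NULL,
                               n_perm = 0L, seed = 1L,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(pairs)) {
    if (is.null(columns)) columns <- names(features)[vapply(features,
                                                            is.numeric,
                                                            logical(1))]
    pairs <- t(utils::combn(columns, 2))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    ok <- stats::complete.cases(features[, c(a, b)])
    x <- features[[a]][ok]; y <- features[[b]][ok]
    n <- length(x)
    res <- data.frame(var1 = a, var2 = b, n = n,
                      spearman_rs = NA_real_, p_t_spearman = NA_real_,
                      kendall_tau_b = NA_real_, p_t_kendall = NA_real_,
                      p_z_kendall = NA_real_,
                      p_perm_spearman = NA_real_, n_permutations = n_perm,
                      seed = seed)
    constant <- n < 3 || length(unique(x)) == 1 || length(unique(y)) == 1
    if (!constant) {
      res$spearman_rs <- cor_spearman(x, y)
      res$p_t_spearman <- cor_p_t(res$spearman_rs, n)
      res$kendall_tau_b <- cor_kendall(x, y)
      res$p_t_kendall <- cor_p_t(res$kendall_tau_b, n)
      res$p_z_kendall <- tau_p_normal(res$kendall_tau_b, n)
      if (n_perm > 0) {
        res$p_perm_spearman <- permutation_p(x, y, "spearman",
                                             n_perm = n_perm,
                                             seed = seed + k)
      }
    }
    res
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_t_spearman_bh <- stats::p.adjust(out$p_t_spearman, "BH")
    out$p_t_kendall_bh <- stats::p.adjust(out$p_t_kendall, "BH")
  }
  out
}
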