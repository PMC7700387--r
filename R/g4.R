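#' Pattern-based G-quadruplex detection
#'
#' Matches the classical quadruplex pattern of four runs of at least
#' `g_run` guanines separated by loops of `loop_min` to `loop_max`
#' arbitrary bases, and merges overlapping matches into maximal regions.
#' `N` bases never count towards a G-run.
#'
#' @param seq nucleotide string (DNA or RNA alphabet).
#' @param g_run minimum G-run length (default 3).
#' @param loop_min,loop_max allowed loop lengths (defaults 1 and 7).
#' @return data.frame with 1-based columns `start`, `end`, `score`
#'   (always 1) and `detector = "pattern"`.
#' @export
pattern_g4 <- function(seq, g_run = 3L, loop_min = 1L, loop_max = 7L) {
  seq <- normalize_sequence(seq)
  runs <- g_runs(seq, min_len = g_run)
  hits <- quad_spans(runs, loop_min, loop_max, max_span = Inf)
  if (nrow(hits) == 0) return(g4_hit_frame("pattern"))
  merged <- merge_intervals(hits$start, hits$end)
  data.frame(start = merged$start, end = merged$end, score = 1,
             detector = "pattern")
}

#' G-score scan for quadruplex candidates
#'
#' Enumerates candidates made of four G-runs (each at least `min_tetrads`
#' long) whose total span does not exceed `max_len`, and scores each as
#' `10 * (tetrads - 2) + (max_len - span) - sum(|loop_i - mean(loop)|)`:
#' more stacked tetrads, compact candidates and even loops score higher.
#' The number of tetrads is the shortest of the four runs (capped at 4).
#' A greedy pass (highest score first, leftmost on ties) reports a
#' non-overlapping candidate set. The scoring formula is this package's
#' own; it preserves the documented qualitative behaviour of published
#' G-score mappers.
#'
#' @inheritParams pattern_g4
#' @param max_len maximal candidate span in nt (default 45).
#' @param min_tetrads minimal G-run length (default 2).
#' @return data.frame with columns `start`, `end`, `tetrads`, `score`,
#'   `detector = "qgrs"`.
#' @export
qgrs_scan <- function(seq, max_len = 45L, min_tetrads = 2L) {
  seq <- normalize_sequence(seq)
  runs <- g_runs(seq, min_len = min_tetrads)
  cand <- quad_spans(runs, loop_min = 1L, loop_max = max_len,
                     max_span = max_len, detail = TRUE)
  if (nrow(cand) == 0) return(g4_hit_frame("qgrs", tetrads = TRUE))
  cand$tetrads <- pmin(cand$min_run, 4L)
  loops <- cbind(cand$loop1, cand$loop2, cand$loop3)
  cand$score <- 10 * (cand$tetrads - 2) + (max_len - (cand$end - cand$start + 1)) -
    rowSums(abs(loops - rowMeans(loops)))
  cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  occupied <- rep(FALSE, nchar(seq))
  for (k in seq_len(nrow(cand))) {
    span <- cand$start[k]:cand$end[k]
    if (!any(occupied[span])) {
      keep[k] <- TRUE
      occupied[span] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  data.frame(start = cand$start, end = cand$end, tetrads = cand$tetrads,
             score = cand$score, detector = "qgrs")
}

#' Sliding-window G-richness score
#'
#' Every base inside a run of k consecutive G scores `min(k, 4)`; inside a
#' C-run, `-min(k, 4)`; otherwise 0. Window means of width `window` are
#' reported, and maximal unions of windows whose mean reaches `threshold`
#' (G side) are called as candidate regions. For sequences shorter than
#' the window the overall mean is returned as a single score. Per-base
#' scores are bounded in `[-4, 4]` and antisymmetric under reverse
#' complementation.
#'
#' @inheritParams pattern_g4
#' @param window window width in nt (default 25).
#' @param threshold region-call threshold on the window mean (default 1.2).
#' @return list with `base_scores`, `window_means` (positions = window
#'   starts) and `regions` (data.frame `start`, `end`, `score` = best
#'   window mean, `detector = "g4hunter"`).
#' @export
g4hunter <- function(seq, window = 25L, threshold = 1.2) {
  seq <- normalize_sequence(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  r <- rle(chars)
  base_scores <- rep(unlist(lapply(seq_along(r$values), function(k) {
    v <- r$values[k]; len <- r$lengths[k]
    if (v == "G") min(len, 4L) else if (v == "C") -min(len, 4L) else 0L
  })), r$lengths)
  if (n < window) {
    wm <- mean(base_scores)
    regions <- if (wm >= threshold)
      data.frame(start = 1L, end = n, score = wm, detector = "g4hunter")
    else g4_hit_frame("g4hunter")
    return(list(base_scores = base_scores, window_means = wm,
                regions = regions))
  }
  cs <- c(0, cumsum(base_scores))
  starts <- seq_len(n - window + 1L)
  wm <- (cs[starts + window] - cs[starts]) / window
  sel <- which(wm >= threshold)
  if (length(sel) == 0) {
    regions <- g4_hit_frame("g4hunter")
  } else {
    merged <- merge_intervals(sel, sel + window - 1L)
    merged$score <- vapply(seq_len(nrow(merged)), function(k) {
      max(wm[sel[sel >= merged$start[k] & sel <= merged$end[k]]])
    }, numeric(1))
    regions <- data.frame(start = merged$start, end = merged$end,
                          score = merged$score, detector = "g4hunter")
  }
  list(base_scores = base_scores, window_means = wm, regions = regions)
}

#' Intersection consensus over G-quadruplex detectors
#'
#' Candidate regions from the pattern detector and the window scorer are
#' intersected first; if the pair shares no interval of at least
#' `min_len` nt, the (pattern, G-score) pair is tried, then (window
#' scorer, G-score). Each reported interval lists every detector with a
#' hit containing it.
#'
#' @param pattern,g4hunter,qgrs hit data.frames with `start`/`end`
#'   columns (as returned by the three detectors; for [g4hunter()] pass
#'   the `regions` element).
#' @param min_len minimal consensus interval length (default 12).
#' @return data.frame with `start`, `end`, `n_supporting`, `detectors`.
#' @export
consensus_g4 <- function(pattern, g4hunter, qgrs, min_len = 12L) {
  hits <- list(pattern = pattern, g4hunter = g4hunter, qgrs = qgrs)
  pairs <- list(c("pattern", "g4hunter"), c("pattern", "qgrs"),
                c("g4hunter", "qgrs"))
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_supporting = integer(0), detectors = character(0))
  for (pr in pairs) {
    a <- hits[[pr[1]]]; b <- hits[[pr[2]]]
    if (is.null(a) || is.null(b) || nrow(a) == 0 || nrow(b) == 0) next
    ivs <- list()
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        s <- max(a$start[i], b$start[j])
        e <- min(a$end[i], b$end[j])
        if (e - s + 1L >= min_len) ivs[[length(ivs) + 1L]] <- c(s, e)
      }
    }
    if (length(ivs) == 0) next
    iv <- unique(do.call(rbind, ivs))
    out <- data.frame(start = iv[, 1], end = iv[, 2])
    out$detectors <- vapply(seq_len(nrow(out)), function(k) {
      supp <- names(hits)[vapply(hits, function(h) {
        !is.null(h) && nrow(h) > 0 &&
          any(h$start <= out$start[k] & h$end >= out$end[k])
      }, logical(1))]
      paste(supp, collapse = "+")
    }, character(1))
    out$n_supporting <- lengths(strsplit(out$detectors, "+", fixed = TRUE))
    return(out[order(out$start), c("start", "end", "n_supporting", "detectors")])
  }
  empty
}

#' Scan a 5'UTR record for consensus G-quadruplex regions
#'
#' Runs the three detectors on the UTR part of a record and reports
#' consensus intervals in sATG-relative coordinates.
#'
#' @param rec a [utr_record()].
#' @param ... passed on to the detectors ([pattern_g4()], [g4hunter()],
#'   [qgrs_scan()] defaults otherwise).
#' @return list with per-detector hits (1-based UTR coordinates) and
#'   `consensus` (sATG-relative `start`/`end`).
#' @export
scan_g4 <- function(rec, ...) {
  stopifnot(inherits(rec, "utr_record"))
  utr <- utr_part(rec)
  p <- pattern_g4(utr)
  h <- g4hunter(utr)$regions
  q <- qgrs_scan(utr)
  cons <- consensus_g4(p, h, q)
  if (nrow(cons) > 0) {
    cons$start <- index_to_satg(cons$start, rec$utr_length)
    cons$end <- index_to_satg(cons$end, rec$utr_length)
  }
  list(pattern = p, g4hunter = h, qgrs = q, consensus = cons)
}

# --- internal helpers ----------------------------------------------------

g4_hit_frame <- function(detector, tetrads = FALSE) {
  out <- data.frame(start = integer(0), end = integer(0))
  if (tetrads) out$tetrads <- integer(0)
  out$score <- numeric(0)
  out$detector <- character(0)
  out
}

# maximal G-runs of at least min_len as data.frame(start, end, len)
g_runs <- function(seq, min_len) {
  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values == "G" & r$lengths >= min_len
  data.frame(start = starts[sel], end = ends[sel], len = r$lengths[sel])
}

# all ordered quadruples of G-runs whose consecutive gaps lie within
# [loop_min, loop_max] and whose span is at most max_span
quad_spans <- function(runs, loop_min, loop_max, max_span, detail = FALSE) {
  n <- nrow(runs)
  out <- list()
  if (n >= 4) {
    nbr <- lapply(seq_len(n), function(j) {
      ks <- integer(0)
      if (j < n) for (k in (j + 1L):n) {
        gap <- runs$start[k] - runs$end[j] - 1L
        if (gap > loop_max) break
        if (gap >= loop_min) ks <- c(ks, k)
      }
      ks
    })
    for (j1 in seq_len(n)) {
      for (j2 in nbr[[j1]]) for (j3 in nbr[[j2]]) for (j4 in nbr[[j3]]) {
        span <- runs$end[j4] - runs$start[j1] + 1L
        if (span > max_span) next
        row <- data.frame(start = runs$start[j1], end = runs$end[j4])
        if (detail) {
          row$min_run <- min(runs$len[c(j1, j2, j3, j4)])
          row$loop1 <- runs$start[j2] - runs$end[j1] - 1L
          row$loop2 <- runs$start[j3] - runs$end[j2] - 1L
          row$loop3 <- runs$start[j4] - runs$end[j3] - 1L
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (length(out) == 0) {
    base <- data.frame(start = integer(0), end = integer(0))
    if (detail) {
      base$min_run <- integer(0)
      base$loop1 <- base$loop2 <- base$loop3 <- integer(0)
    }
    return(base)
  }
  do.call(rbind, out)
}

# merge overlapping/adjacent-overlapping integer intervals
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- integer(0); oute <- integer(0)
  for (k in seq_along(start)[-1]) {
    if (start[k] <= me + 0L) {
      me <- max(me, end[k])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[k]; me <- end[k]
    }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}
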