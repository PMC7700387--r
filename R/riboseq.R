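#' Per-base ribosome-profiling coverage track
#'
#' Holds nonnegative per-base counts over a window spanning the whole
#' 5'UTR and at least the first 90 nt (30 codons) of the main ORF.
#' Position i of `counts` is TSS-relative base i.
#'
#' @param transcript_id identifier.
#' @param counts numeric vector of per-base counts.
#' @param utr_length 5'UTR length; the track must extend at least 90 nt
#'   beyond it.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(transcript_id, counts, utr_length) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("coverage counts must be nonnegative", call. = FALSE)
  }
  if (length(counts) < utr_length + 90L) {
    stop("track must cover the 5'UTR plus at least the first 90 nt of the ",
         "main ORF", call. = FALSE)
  }
  structure(list(transcript_id = transcript_id, counts = counts,
                 utr_length = as.integer(utr_length)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track ", x$transcript_id, ": ", length(x$counts),
      " nt, mean depth ", signif(mean(x$counts), 4), "\n", sep = "")
  invisible(x)
}

#' Read a bedGraph coverage file into a track
#'
#' The bedGraph must be in transcript coordinates (TSS-relative; the
#' chrom field carries the transcript ID). Wiggle files are accepted too.
#'
#' @param path bedGraph/wig file.
#' @param transcript_id transcript to extract.
#' @param utr_length 5'UTR length of that transcript.
#' @param track_length total track length; defaults to the last covered
#'   base.
#' @export
read_bedgraph <- function(path, transcript_id, utr_length,
                          track_length = NULL) {
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == transcript_id]
  if (length(gr) == 0) {
    stop("transcript ", transcript_id, " not found in ", path, call. = FALSE)
  }
  if (is.null(track_length)) track_length <- max(GenomicRanges::end(gr))
  counts <- numeric(track_length)
  for (k in seq_along(gr)) {
    counts[GenomicRanges::start(gr)[k]:GenomicRanges::end(gr)[k]] <-
      gr$score[k]
  }
  coverage_track(transcript_id, counts, utr_length)
}

#' Write a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  df <- data.frame(chrom = track$transcript_id, start = starts - 1L,
                   end = ends, score = r$values)
  df <- df[df$score != 0, , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Coverage of a region relative to a reference region
#'
#' Returns `100 * mean(region) / mean(reference)`. Both intervals are
#' sATG-relative; the reference defaults to the first 30 codons of the
#' main ORF (+1..+90). Scale-invariant: multiplying the whole track by a
#' positive constant leaves the result unchanged.
#'
#' @param track a [coverage_track()].
#' @param region integer `c(start, end)` in sATG coordinates.
#' @param reference integer `c(start, end)`; default `c(1, 90)`.
#' @return percentage (numeric scalar).
#' @export
relative_coverage <- function(track, region, reference = c(1L, 90L)) {
  stopifnot(inherits(track, "coverage_track"))
  idx <- function(iv) {
    i <- satg_to_index(iv[1], track$utr_length):satg_to_index(iv[2],
                                                              track$utr_length)
    if (min(i) < 1L || max(i) > length(track$counts)) {
      stop("interval ", iv[1], "..", iv[2], " outside the coverage track",
           call. = FALSE)
    }
    i
  }
  ref_mean <- mean(track$counts[idx(reference)])
  if (ref_mean == 0) {
    stop("reference region has zero coverage; relative coverage undefined",
         call. = FALSE)
  }
  100 * mean(track$counts[idx(region)]) / ref_mean
}

#' Qualitative occupancy bin
#'
#' Bins a relative-coverage percentage: 1 low (< 25%), 2 medium (25% to
#' 75%, both bounds included), 3 high (> 75%).
#'
#' @param rel nonnegative percentage.
#' @return integer bin 1-3.
#' @export
qualitative_bin <- function(rel) {
  if (any(is.na(rel)) || any(rel < 0)) {
    stop("relative coverage must be nonnegative", call. = FALSE)
  }
  as.integer(ifelse(rel < 25, 1L, ifelse(rel <= 75, 2L, 3L)))
}
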