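#' Coordinate systems for 5'UTR features
#'
#' Feature positions are stored relative to the A of the main-ORF start
#' codon (sATG): the A of the sATG is +1 and the base immediately 5' of it
#' is -1; there is no coordinate 0. `satg_to_tss()` converts an upstream
#' sATG-relative position to a 1-based position from the transcription
#' start site (first transcribed base = 1), and `tss_to_satg()` is its
#' inverse.
#'
#' @param pos integer vector of sATG-relative positions (no zero).
#' @param pos_tss integer vector of 1-based TSS-relative positions.
#' @param utr_length length of the 5'UTR in nucleotides.
#' @return an integer vector of converted positions.
#' @examples
#' satg_to_tss(-694, 694)  # first UTR base -> 1
#' satg_to_tss(-1, 694)    # last UTR base -> utr_length
#' tss_to_satg(225, 313)   # -> -89
#' @export
satg_to_tss <- function(pos, utr_length) {
  pos <- check_satg_pos(pos)
  if (any(pos > -1L | pos < -utr_length)) {
    stop("sATG-relative position outside the 5'UTR [-", utr_length, ", -1]",
         call. = FALSE)
  }
  as.integer(utr_length + pos + 1L)
}

#' @rdname satg_to_tss
#' @export
tss_to_satg <- function(pos_tss, utr_length) {
  pos_tss <- as.integer(pos_tss)
  if (any(is.na(pos_tss)) || any(pos_tss < 1L | pos_tss > utr_length)) {
    stop("TSS-relative position outside [1, ", utr_length, "]", call. = FALSE)
  }
  as.integer(pos_tss - utr_length - 1L)
}

check_satg_pos <- function(pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos))) stop("position is NA", call. = FALSE)
  if (any(pos == 0L)) {
    stop("coordinate 0 does not exist in sATG-relative coordinates",
         call. = FALSE)
  }
  pos
}

# Map the signed no-zero scale onto contiguous integers (-1 -> -1, +1 -> 0)
# so that interval arithmetic is ordinary integer arithmetic.
satg_to_linear <- function(pos) {
  pos <- check_satg_pos(pos)
  ifelse(pos > 0L, pos - 1L, pos)
}

linear_to_satg <- function(lin) {
  lin <- as.integer(lin)
  ifelse(lin >= 0L, lin + 1L, lin)
}

#' Inclusive length of a feature interval in sATG-relative coordinates
#'
#' Coordinate 0 does not exist, so an interval spanning the sATG (negative
#' start, positive end) is one shorter than naive subtraction suggests:
#' the interval -3..+3 contains 6 bases.
#'
#' @param start,end interval bounds in sATG-relative coordinates
#'   (`start <= end` in signed order); vectors are recycled.
#' @return integer vector of inclusive nucleotide counts.
#' @examples
#' interval_length(-525, -376)  # 150
#' interval_length(-3, 3)       # 6, no coordinate 0
#' @export
interval_length <- function(start, end) {
  s <- satg_to_linear(start)
  e <- satg_to_linear(end)
  if (any(s > e)) stop("interval start is 3' of its end", call. = FALSE)
  as.integer(e - s + 1L)
}

#' Construct a validated feature interval
#'
#' @param start,end sATG-relative bounds. `end` may be `NA` for an
#'   open-ended interval that extends past the sATG (printed as ">+1").
#' @param open_ended flag marking an interval extending past the sATG.
#' @return a list with elements `start`, `end`, `open_ended`, `length`.
#' @export
feature_interval <- function(start, end = NA, open_ended = is.na(end)) {
  start <- check_satg_pos(start)
  if (!open_ended) {
    len <- interval_length(start, end)
  } else {
    if (start > 0L) stop("open-ended interval must start upstream", call. = FALSE)
    end <- NA_integer_
    len <- NA_integer_
  }
  list(start = start, end = if (open_ended) NA_integer_ else as.integer(end),
       open_ended = open_ended, length = len)
}

# Intersection of two sATG-coordinate intervals; NULL when empty.
interval_intersect <- function(s1, e1, s2, e2) {
  a <- max(satg_to_linear(s1), satg_to_linear(s2))
  b <- min(satg_to_linear(e1), satg_to_linear(e2))
  if (a > b) return(NULL)
  c(linear_to_satg(a), linear_to_satg(b))
}
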