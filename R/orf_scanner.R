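#' Find all upstream ATG codons in a 5'UTR
#'
#' Reports every ATG triplet lying entirely within the 5'UTR (triplets
#' straddling the sATG are excluded), 5' to 3', with positions on both
#' coordinate systems and the flanking-context category. `N` bases never
#' match. TIS scores from an external initiation-site predictor may be
#' supplied per position and are binned with [bin_tis()].
#'
#' @param rec a [utr_record()].
#' @param tis_scores optional data.frame with columns `pos` (sATG-relative)
#'   and `score` in `[0, 1]`.
#' @return data.frame with columns `gene_id`, `pos_satg`, `pos_tss`,
#'   `context_category`, `truncated_context`, `tis_score`, `tis_bin`,
#'   `starts_uorf` (NA here; filled by [scan_utr()]).
#' @seealso [find_uorfs()], [classify_context()]
#' @export
scan_uatgs <- function(rec, tis_scores = NULL) {
  stopifnot(inherits(rec, "utr_record"))
  utr <- utr_part(rec)
  hits <- gregexpr("ATG", utr, fixed = TRUE)[[1]]
  empty <- data.frame(gene_id = character(0), pos_satg = integer(0),
                      pos_tss = integer(0), context_category = integer(0),
                      truncated_context = logical(0), tis_score = numeric(0),
                      tis_bin = integer(0), starts_uorf = logical(0))
  if (hits[1] == -1L) return(empty)
  idx <- as.integer(hits)
  pos <- index_to_satg(idx, rec$utr_length)
  ctx <- vapply(idx, function(i) context_category_at(rec$sequence, i),
                integer(1))
  trunc <- vapply(idx, function(i) {
    i - 3L < 1L || i + 3L > nchar(rec$sequence)
  }, logical(1))
  out <- data.frame(gene_id = rec$gene_id, pos_satg = pos,
                    pos_tss = satg_to_tss(pos, rec$utr_length),
                    context_category = ctx, truncated_context = trunc,
                    tis_score = NA_real_, tis_bin = NA_integer_,
                    starts_uorf = NA)
  if (!is.null(tis_scores)) {
    m <- match(out$pos_satg, tis_scores$pos)
    out$tis_score <- tis_scores$score[m]
    has <- !is.na(out$tis_score)
    out$tis_bin[has] <- bin_tis(out$tis_score[has])
  }
  out[order(out$pos_satg), , drop = FALSE]
}

# context of the ATG whose A sits at sequence index i
context_category_at <- function(sequence, i) {
  n <- nchar(sequence)
  m3 <- if (i - 3L >= 1L) substr(sequence, i - 3L, i - 3L) else NA_character_
  p4 <- if (i + 3L <= n) substr(sequence, i + 3L, i + 3L) else NA_character_
  m3_fav <- !is.na(m3) && m3 %in% c("A", "G")
  p4_fav <- !is.na(p4) && p4 == "G"
  if (is.na(m3) || is.na(p4)) {
    # truncated context near a transcript end: grade on the visible key base
    return(if (m3_fav || p4_fav) 2L else 1L)
  }
  if (m3_fav && p4_fav) {
    full <- if (i - 6L >= 1L) substr(sequence, i - 6L, i + 3L) else ""
    if (grepl("^GCC[AG]CCATGG$", full)) return(4L)
    return(3L)
  }
  if (m3_fav || p4_fav) return(2L)
  1L
}

#' Grade the flanking (Kozak) context of an ATG
#'
#' The key positions are -3 (favourable: A or G) and +4 (favourable: G),
#' counted from the A of the ATG as +1. Categories: 1 weak (neither key
#' base favourable), 2 adequate (exactly one), 3 strong (both), 4 optimal
#' (the full `GCC(A/G)CCATGG` motif).
#'
#' @param window context string containing the ATG; by default a 10-nt
#'   window covering positions -6..+4 with the ATG at characters 7-9.
#'   Shorter windows (a transcript end clipping the -6..-4 side) are
#'   right-anchored at +4.
#' @param atg_at character offset of the A within `window`.
#' @return integer category 1-4.
#' @examples
#' classify_context("GCCACCATGG")  # 4, optimal
#' classify_context("AAAGAAATGG")  # 3, strong
#' classify_context("AAACAAATGG")  # 2, adequate
#' classify_context("AAATAAATGC")  # 1, weak
#' @export
classify_context <- function(window, atg_at = nchar(window) - 3L) {
  window <- normalize_sequence(window, "context window")
  if (substr(window, atg_at, atg_at + 2L) != "ATG") {
    stop("no ATG at the stated position of the context window", call. = FALSE)
  }
  context_category_at(window, atg_at)
}

#' Bin a translation-initiation-site score
#'
#' Scores come from an external TIS predictor on `[0, 1]`; bins are
#' 1 = low (< 0.1), 2 = middle (0.1 to 0.5, both bounds included),
#' 3 = high (> 0.5).
#'
#' @param score numeric in `[0, 1]`.
#' @return integer bin 1-3.
#' @export
bin_tis <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    stop("TIS score must lie in [0, 1]", call. = FALSE)
  }
  as.integer(ifelse(score < 0.1, 1L, ifelse(score <= 0.5, 2L, 3L)))
}

#' Find upstream open reading frames
#'
#' Each uATG is extended codon by codon through the 5'UTR and the whole
#' supplied CDS prefix. The first in-frame stop (TAA/TAG/TGA) closes the
#' uORF (stop codon included in its length); a uORF whose stop lies past
#' the sATG, or that never meets a stop in the available sequence, is
#' flagged as overlapping the main ORF. Unterminated uORFs are reported
#' open-ended with a lower-bound length equal to the complete in-frame
#' codons available. Closed uORFs shorter than `min_len_nt` are
#' suppressed; nested and overlapping uORFs are all reported, sorted by
#' `(start, end)`.
#'
#' @param rec a [utr_record()].
#' @param min_len_nt minimum closed-uORF length in nt (default 30).
#' @return data.frame with columns `gene_id`, `start`, `end` (NA when
#'   open-ended), `open_ended`, `length_nt`, `frame_vs_morf`,
#'   `overlaps_morf`.
#' @export
find_uorfs <- function(rec, min_len_nt = 30L) {
  stopifnot(inherits(rec, "utr_record"))
  uatgs <- scan_uatgs(rec)
  n <- nchar(rec$sequence)
  L <- rec$utr_length
  rows <- lapply(uatgs$pos_satg, function(p) {
    i <- satg_to_index(p, L)
    j <- i
    while (j + 2L <= n) {
      codon <- substr(rec$sequence, j, j + 2L)
      if (codon %in% .stop_codons) {
        end_satg <- index_to_satg(j + 2L, L)
        len <- interval_length(p, end_satg)
        if (len < min_len_nt) return(NULL)
        return(data.frame(gene_id = rec$gene_id, start = p, end = end_satg,
                          open_ended = FALSE, length_nt = len,
                          frame_vs_morf = (L + 1L - i) %% 3L,
                          overlaps_morf = j + 2L > L))
      }
      j <- j + 3L
    }
    data.frame(gene_id = rec$gene_id, start = p, end = NA_integer_,
               open_ended = TRUE, length_nt = 3L * ((n - i + 1L) %/% 3L),
               frame_vs_morf = (L + 1L - i) %% 3L, overlaps_morf = TRUE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), open_ended = logical(0),
                      length_nt = integer(0), frame_vs_morf = integer(0),
                      overlaps_morf = logical(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, na.last = FALSE), , drop = FALSE]
}

#' Scan a 5'UTR for uATGs and uORFs in one pass
#'
#' @inheritParams find_uorfs
#' @inheritParams scan_uatgs
#' @return list with elements `uatgs` (with `starts_uorf` filled) and
#'   `uorfs`.
#' @export
scan_utr <- function(rec, min_len_nt = 30L, tis_scores = NULL) {
  uatgs <- scan_uatgs(rec, tis_scores = tis_scores)
  uorfs <- find_uorfs(rec, min_len_nt = min_len_nt)
  uatgs$starts_uorf <- uatgs$pos_satg %in% uorfs$start
  list(uatgs = uatgs, uorfs = uorfs)
}
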