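#' Write and read feature tables as BED6 / GFF3
#'
#' Features held in sATG-relative coordinates are converted to
#' TSS-relative transcript coordinates for export: GFF3 is 1-based
#' inclusive, BED is 0-based half-open (the conversion is the writer's
#' job and round-trips through the readers). Open-ended intervals are
#' exported up to the base before the sATG.
#'
#' @param features data.frame with columns `transcript_id`, `start`,
#'   `end` (sATG-relative; `end` may be NA for open-ended features),
#'   `name` and optionally `score`, `type`.
#' @param utr_lengths named integer vector of 5'UTR lengths per
#'   transcript.
#' @param path output file.
#' @return (readers) a data.frame in the same sATG-relative layout.
#' @export
write_features_bed <- function(features, utr_lengths, path) {
  gr <- features_to_granges(features, utr_lengths)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_features_bed
#' @export
read_features_bed <- function(path, utr_lengths) {
  gr <- rtracklayer::import(path, format = "bed")
  granges_to_features(gr, utr_lengths)
}

#' @rdname write_features_bed
#' @export
write_features_gff3 <- function(features, utr_lengths, path) {
  gr <- features_to_granges(features, utr_lengths)
  gr$type <- if (!is.null(features$type)) features$type else "sequence_feature"
  gr$source <- "utr5scan"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_features_bed
#' @export
read_features_gff3 <- function(path, utr_lengths) {
  gr <- rtracklayer::import(path, format = "gff3")
  out <- granges_to_features(gr, utr_lengths)
  out$type <- as.character(gr$type)
  out
}

features_to_granges <- function(features, utr_lengths) {
  L <- utr_lengths[features$transcript_id]
  if (any(is.na(L))) {
    stop("missing utr_length for transcript(s): ",
         paste(unique(features$transcript_id[is.na(L)]), collapse = ", "),
         call. = FALSE)
  }
  end <- ifelse(is.na(features$end), -1L, features$end)
  gr <- GenomicRanges::GRanges(
    seqnames = features$transcript_id,
    ranges = IRanges::IRanges(
      start = unname(L) + satg_to_linear(features$start) + 1L,
      end = unname(L) + satg_to_linear(end) + 1L),
    strand = "+")
  gr$name <- features$name
  gr$score <- if (!is.null(features$score)) features$score else 0
  gr
}

granges_to_features <- function(gr, utr_lengths) {
  tx <- as.character(GenomicRanges::seqnames(gr))
  L <- unname(utr_lengths[tx])
  data.frame(transcript_id = tx,
             start = linear_to_satg(GenomicRanges::start(gr) - L - 1L),
             end = linear_to_satg(GenomicRanges::end(gr) - L - 1L),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
             stringsAsFactors = FALSE)
}
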