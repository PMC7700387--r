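#' A single transcript's spliced 5'UTR record
#'
#' Holds the spliced 5'UTR sequence in mRNA orientation, optionally
#' followed by a prefix of the coding sequence (used to extend uORF stop
#' searches past the sATG). Sequences are normalised to the uppercase DNA
#' alphabet (U is converted to T). Intron annotations record where an
#' intron was removed, as the sATG-relative position of the last UTR base
#' of the 5' exon, together with the intron's genomic length.
#'
#' @param gene_id,transcript_id identifiers.
#' @param sequence nucleotide string, 5' to 3'.
#' @param utr_length 5'UTR length in nt; defaults to the full sequence
#'   length minus `cds_prefix_length`.
#' @param cds_prefix_length number of CDS bases included after the UTR
#'   (0 if absent); if >= 3, the prefix must begin with ATG.
#' @param introns `NULL` or a data.frame with columns `position`
#'   (sATG-relative, in `[-utr_length, -1]`) and `length` (nt).
#' @param species_group one of `"human"`, `"primates"`, `"rodents"`,
#'   `"other_placental"`, `"sauropsids"`, `"fishes"`.
#' @return an object of class `utr_record`.
#' @examples
#' rec <- utr_record("GENE", "TX1", "CCATGCCTTTT", utr_length = 11)
#' rec$utr_length
#' @export
utr_record <- function(gene_id, transcript_id, sequence, utr_length = NULL,
                       cds_prefix_length = 0L, introns = NULL,
                       species_group = "human") {
  sequence <- normalize_sequence(sequence,
                                 paste0("sequence of ", transcript_id))
  cds_prefix_length <- as.integer(cds_prefix_length)
  if (is.null(utr_length)) utr_length <- nchar(sequence) - cds_prefix_length
  utr_length <- as.integer(utr_length)
  if (utr_length + cds_prefix_length != nchar(sequence)) {
    stop("utr_length + cds_prefix_length must equal the sequence length (",
         transcript_id, ")", call. = FALSE)
  }
  if (cds_prefix_length >= 3L &&
      substr(sequence, utr_length + 1L, utr_length + 3L) != "ATG") {
    stop("sATG not found: CDS prefix of ", transcript_id,
         " does not start with ATG", call. = FALSE)
  }
  if (!is.null(introns)) {
    introns <- as.data.frame(introns)
    stopifnot(all(c("position", "length") %in% names(introns)))
    introns$position <- check_satg_pos(introns$position)
    if (any(introns$position < -utr_length | introns$position > -1L)) {
      stop("intron positions must lie within [-utr_length, -1] (",
           transcript_id, ")", call. = FALSE)
    }
  } else {
    introns <- data.frame(position = integer(0), length = integer(0))
  }
  species_group <- match.arg(species_group,
                             c("human", "primates", "rodents",
                               "other_placental", "sauropsids", "fishes"))
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 sequence = sequence, utr_length = utr_length,
                 cds_prefix_length = cds_prefix_length, introns = introns,
                 species_group = species_group),
            class = "utr_record")
}

#' @export
print.utr_record <- function(x, ...) {
  cat("utr_record ", x$transcript_id, " (", x$gene_id, "): ",
      x$utr_length, " nt 5'UTR",
      if (x$cds_prefix_length > 0)
        paste0(" + ", x$cds_prefix_length, " nt CDS prefix"),
      ", ", nrow(x$introns), " intron(s)\n", sep = "")
  invisible(x)
}

utr_part <- function(rec) substr(rec$sequence, 1L, rec$utr_length)

# sequence index (1-based within rec$sequence) of an sATG coordinate
satg_to_index <- function(pos, utr_length) {
  utr_length + satg_to_linear(pos) + 1L
}

index_to_satg <- function(i, utr_length) {
  linear_to_satg(as.integer(i) - utr_length - 1L)
}

#' Read 5'UTR records from FASTA plus a per-transcript annotation table
#'
#' The FASTA headers (first whitespace-delimited word) must match the
#' `transcript` column of the annotation table. The annotation table is a
#' TSV with columns `gene`, `transcript`, `utr_length`,
#' `cds_prefix_length`, and optionally `intron_positions` /
#' `intron_lengths` (comma-separated), `species_group`,
#' `tissue_distribution`, `mode_expression`, `tis_score`.
#'
#' @param fasta path to the FASTA file.
#' @param annotation path to the annotation TSV (or a data.frame).
#' @return a named list of [utr_record()] objects (names = transcript IDs),
#'   with the remaining annotation columns attached as attribute `"meta"`.
#' @export
read_utr_fasta <- function(fasta, annotation) {
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- read_annotation_table(annotation)
  missing_ann <- setdiff(ids, ann$transcript)
  if (length(missing_ann) > 0) {
    stop("FASTA record(s) absent from the annotation table: ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  }
  missing_seq <- setdiff(ann$transcript, ids)
  if (length(missing_seq) > 0) {
    stop("annotation row(s) without a FASTA record: ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  }
  recs <- lapply(seq_along(ids), function(k) {
    row <- ann[ann$transcript == ids[k], , drop = FALSE][1, ]
    introns <- NULL
    if (!is.null(row$intron_positions) && !is.na(row$intron_positions) &&
        nzchar(row$intron_positions)) {
      introns <- data.frame(
        position = as.integer(strsplit(as.character(row$intron_positions), ",")[[1]]),
        length = as.integer(strsplit(as.character(row$intron_lengths), ",")[[1]]))
    }
    utr_record(gene_id = row$gene, transcript_id = ids[k],
               sequence = as.character(seqs[[k]]),
               utr_length = row$utr_length,
               cds_prefix_length = if (is.null(row$cds_prefix_length) ||
                                       is.na(row$cds_prefix_length)) 0L
                                   else row$cds_prefix_length,
               introns = introns,
               species_group = if (is.null(row$species_group) ||
                                   is.na(row$species_group)) "human"
                               else row$species_group)
  })
  names(recs) <- ids
  attr(recs, "meta") <- ann
  recs
}

#' @rdname read_utr_fasta
#' @export
read_annotation_table <- function(annotation) {
  ann <- if (is.data.frame(annotation)) annotation
         else read.delim(annotation, stringsAsFactors = FALSE)
  required <- c("gene", "transcript", "utr_length")
  miss <- setdiff(required, names(ann))
  if (length(miss) > 0) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' Write 5'UTR records back to FASTA and an annotation table
#'
#' Round-trips with [read_utr_fasta()]: sequences and metadata are
#' preserved exactly.
#'
#' @param records list of [utr_record()] objects.
#' @param fasta,annotation output paths (`annotation = NULL` skips the table).
#' @param rna write sequences in the RNA alphabet (T -> U).
#' @export
write_utr_fasta <- function(records, fasta, annotation = NULL, rna = FALSE) {
  lines <- unlist(lapply(records, function(r) {
    s <- r$sequence
    if (rna) s <- chartr("T", "U", s)
    c(paste0(">", r$transcript_id), s)
  }))
  writeLines(lines, fasta)
  if (!is.null(annotation)) {
    ann <- do.call(rbind, lapply(records, function(r) {
      data.frame(gene = r$gene_id, transcript = r$transcript_id,
                 utr_length = r$utr_length,
                 cds_prefix_length = r$cds_prefix_length,
                 intron_positions = paste(r$introns$position, collapse = ","),
                 intron_lengths = paste(r$introns$length, collapse = ","),
                 species_group = r$species_group,
                 stringsAsFactors = FALSE)
    }))
    write.table(ann, annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}
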