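#' Classify a 5'UTR variant against the feature map
#'
#' Classes (several may co-occur): `uorf_start_disruption` when the
#' variant changes any of the three uATG bases of a uORF start away from
#' ATG (an indel touching the start triplet always disrupts it);
#' `within_uorf` when the affected interval intersects a uORF
#' (open-ended uORFs extend to the base before the sATG) and the variant
#' does not disrupt a uORF start; `within_uatg`, `within_conserved_region`
#' and `within_rg4` by interval intersection; `none` when nothing applies.
#' For SNVs inside a uORF and with the record sequence supplied, the
#' coding effect is evaluated in the uORF's own frame (synonymous /
#' nonsynonymous / stop_gain / stop_loss); indels of length not divisible
#' by three are frameshifts; otherwise the effect is `not_evaluated`.
#'
#' @param pos sATG-relative position of the variant's first affected
#'   (or anchor) base.
#' @param ref,alt reference and alternative alleles in transcript
#'   orientation (SNV or small indel; insertions keep the anchor base in
#'   both, VCF style).
#' @param features list with data.frame elements `uorfs` (`start`, `end`,
#'   `open_ended`), `uatgs` (`pos`), `conserved` (`start`, `end`) and
#'   `rg4` (`start`, `end`); missing elements are treated as empty.
#' @param sequence optional full record sequence (UTR + CDS prefix) for
#'   coding-effect evaluation and reference-allele checking.
#' @param utr_length 5'UTR length; required with `sequence`.
#' @return list with `classes` (character vector), `coding_effect` and
#'   `uorf_hits` (indices into `features$uorfs`).
#' @export
classify_variant <- function(pos, ref, alt, features, sequence = NULL,
                             utr_length = NULL) {
  pos <- check_satg_pos(pos)
  ref <- normalize_sequence(ref, "ref allele")
  alt <- normalize_sequence(alt, "alt allele")
  if (!is.null(sequence) && is.null(utr_length)) {
    stop("utr_length is required when sequence is supplied", call. = FALSE)
  }
  ext_start <- satg_to_linear(pos)
  ext_end <- ext_start + nchar(ref) - 1L
  if (!is.null(sequence)) {
    idx <- utr_length + ext_start + 1L
    seen <- substr(sequence, idx, idx + nchar(ref) - 1L)
    if (seen != ref) {
      stop("reference allele mismatch at position ", pos, ": sequence has ",
           seen, ", variant says ", ref, call. = FALSE)
    }
  }
  uorfs <- features$uorfs
  classes <- character(0)
  coding_effect <- NA_character_
  uorf_hits <- integer(0)
  disrupted <- FALSE
  if (!is.null(uorfs) && nrow(uorfs) > 0) {
    for (k in seq_len(nrow(uorfs))) {
      s <- satg_to_linear(uorfs$start[k])
      is_open <- isTRUE(uorfs$open_ended[k]) || is.na(uorfs$end[k])
      e <- if (is_open) -1L else satg_to_linear(uorfs$end[k])
      # start-codon triplet
      if (ext_end >= s && ext_start <= s + 2L) {
        if (nchar(ref) != nchar(alt) || nchar(ref) > 1L) {
          disrupted <- TRUE
        } else {
          off <- ext_start - s
          trip <- strsplit("ATG", "")[[1]]
          trip[off + 1L] <- alt
          if (paste(trip, collapse = "") != "ATG") disrupted <- TRUE
        }
      }
      if (ext_start <= e && ext_end >= s) uorf_hits <- c(uorf_hits, k)
    }
  }
  if (disrupted) {
    classes <- c(classes, "uorf_start_disruption")
  } else if (length(uorf_hits) > 0) {
    classes <- c(classes, "within_uorf")
    coding_effect <- "not_evaluated"
    if (nchar(ref) != nchar(alt)) {
      if (abs(nchar(ref) - nchar(alt)) %% 3L != 0L) {
        coding_effect <- "frameshift"
      }
    } else if (nchar(ref) == 1L && !is.null(sequence)) {
      k <- uorf_hits[1]
      s <- satg_to_linear(uorfs$start[k])
      codon_i <- (ext_start - s) %/% 3L
      codon_idx <- utr_length + s + 3L * codon_i + 1L
      ref_codon <- substr(sequence, codon_idx, codon_idx + 2L)
      off_in_codon <- (ext_start - s) %% 3L
      alt_codon <- ref_codon
      substr(alt_codon, off_in_codon + 1L, off_in_codon + 1L) <- alt
      coding_effect <- codon_effect(ref_codon, alt_codon)
    }
  }
  if (hits_any(ext_start, ext_end, features$uatgs$pos,
               features$uatgs$pos + 2L, triplet = TRUE)) {
    classes <- c(classes, "within_uatg")
  }
  if (hits_any(ext_start, ext_end, features$conserved$start,
               features$conserved$end)) {
    classes <- c(classes, "within_conserved_region")
  }
  if (hits_any(ext_start, ext_end, features$rg4$start, features$rg4$end)) {
    classes <- c(classes, "within_rg4")
  }
  if (length(classes) == 0) classes <- "none"
  list(classes = classes, coding_effect = coding_effect,
       uorf_hits = uorf_hits)
}

hits_any <- function(ext_start, ext_end, starts, ends, triplet = FALSE) {
  if (is.null(starts) || length(starts) == 0) return(FALSE)
  s <- satg_to_linear(starts)
  e <- if (triplet) s + 2L else satg_to_linear(ends)
  any(ext_start <= e & ext_end >= s)
}

codon_effect <- function(ref_codon, alt_codon) {
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  if (is.na(ref_aa) || is.na(alt_aa)) return("not_evaluated")
  if (ref_aa == alt_aa) return("synonymous")
  if (alt_aa == "*") return("stop_gain")
  if (ref_aa == "*") return("stop_loss")
  "nonsynonymous"
}

#' Classify a table of variants
#'
#' @param variants data.frame with columns `pos`, `ref`, `alt` (transcript
#'   orientation) and optionally `gene_id`/`rsid`.
#' @inheritParams classify_variant
#' @return the input with added columns `classes` (collapsed with `+`)
#'   and `coding_effect`.
#' @export
classify_variants <- function(variants, features, sequence = NULL,
                              utr_length = NULL) {
  res <- lapply(seq_len(nrow(variants)), function(k) {
    classify_variant(variants$pos[k], variants$ref[k], variants$alt[k],
                     features, sequence = sequence, utr_length = utr_length)
  })
  variants$classes <- vapply(res, function(r) paste(r$classes, collapse = "+"),
                             character(1))
  variants$coding_effect <- vapply(res, function(r) r$coding_effect,
                                   character(1))
  variants
}

.variant_classes <- c("uorf_start_disruption", "within_uorf", "within_uatg",
                      "within_conserved_region", "within_rg4", "none")

#' Tally classified variants per class
#'
#' Each variant counts at most once per class (membership in several
#' overlapping uORFs still counts once), and a start-disrupting variant
#' is never also counted as within a uORF.
#'
#' @param classified result of [classify_variants()] (needs a `classes`
#'   column).
#' @return named integer vector over all classes.
#' @export
count_by_class <- function(classified) {
  lists <- strsplit(classified$classes, "+", fixed = TRUE)
  vapply(setNames(.variant_classes, .variant_classes), function(cl) {
    sum(vapply(lists, function(v) cl %in% v, logical(1)))
  }, integer(1))
}

#' Convert printed genomic alleles to transcript orientation
#'
#' Variants reported with genomic alleles for a minus-strand gene are
#' complemented (not reverse-complemented: positions already follow the
#' transcript) so that `ref`/`alt` read in mRNA orientation.
#'
#' @param variants data.frame with `ref`, `alt` and `strand` columns.
#' @return the data.frame with complemented alleles where `strand == "-"`.
#' @export
to_transcript_alleles <- function(variants) {
  flip <- variants$strand == "-"
  variants$ref[flip] <- chartr("ACGTN", "TGCAN", variants$ref[flip])
  variants$alt[flip] <- chartr("ACGTN", "TGCAN", variants$alt[flip])
  variants
}

#' Read a variant table
#'
#' Reads either a TSV with sATG-relative positions (columns `gene`,
#' `pos`, `ref`, `alt`, optional `rsid`, `strand`) or a minimal VCF whose
#' CHROM column carries the transcript ID and POS is TSS-relative
#' 1-based (converted using `utr_lengths`).
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param utr_lengths named vector of UTR lengths (required for VCF).
#' @return data.frame with sATG-relative `pos`.
#' @export
read_variants <- function(path, format = c("tsv", "vcf"),
                          utr_lengths = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    return(read.delim(path, stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- sub("^#", "", lines[1])
  body <- read.delim(text = paste(c(header, lines[-1]), collapse = "\n"),
                     stringsAsFactors = FALSE)
  if (is.null(utr_lengths)) stop("utr_lengths required for VCF input",
                                 call. = FALSE)
  data.frame(gene = body$CHROM,
             pos = tss_to_satg(body$POS, utr_lengths[body$CHROM]),
             ref = body$REF, alt = body$ALT,
             rsid = if ("ID" %in% names(body)) body$ID else NA_character_,
             stringsAsFactors = FALSE)
}
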