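#' Bundled reference annotation of the human ABCA-subfamily 5'UTRs
#'
#' Curated feature annotations of the 5'UTRs of the principal transcript
#' isoforms of the 12 human ABCA transporter genes, as reported in the
#' literature: the per-gene feature counts (with protein tissue
#' distribution and mode expression scores, NA where not annotated), the
#' uORF intervals with qualitative ribosome-profiling coverage bins
#' (1 low / 2 medium / 3 high), the uATG positions with conservation
#' category (0-5), flanking-context category (1-4) and TIS bin (1-3),
#' the 5'UTR intron lengths, the most conserved subregions (where a
#' single interval was reported), candidate RNA G-quadruplex regions,
#' and 13 single-nucleotide variants observed in a breast-cancer cohort
#' (alleles as printed, i.e. genomic: use [to_transcript_alleles()] with
#' the `strand` column before classification). All positions are
#' sATG-relative. These tables serve as worked examples and regression
#' fixtures; the reported G-quadruplex regions, stem-loop counts and
#' coverage bins derive from external predictors and data, so they
#' document the published annotation rather than this package's detector
#' output.
#'
#' @param name which table: `"features"`, `"uorfs"`, `"uatgs"`,
#'   `"introns"`, `"conserved_regions"`, `"rg4_regions"`, `"variants"`.
#' @return a data.frame.
#' @examples
#' head(abca_table("uorfs"))
#' @export
abca_table <- function(name = c("features", "uorfs", "uatgs", "introns",
                                "conserved_regions", "rg4_regions",
                                "variants")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("abca_", name, ".tsv"),
                      package = "utr5scan", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble the feature map of one ABCA gene for variant annotation
#'
#' Collects the bundled uORF intervals, uATG positions, conserved
#' subregions and G-quadruplex regions of a gene in the list layout
#' consumed by [classify_variant()].
#'
#' @param gene gene symbol, e.g. `"ABCA10"`.
#' @return list with `uorfs`, `uatgs`, `conserved`, `rg4`.
#' @export
abca_gene_features <- function(gene) {
  pick <- function(tab) tab[tab$gene == gene, , drop = FALSE]
  uorfs <- pick(abca_table("uorfs"))
  list(uorfs = data.frame(start = uorfs$start, end = uorfs$end,
                          open_ended = uorfs$open_ended),
       uatgs = data.frame(pos = pick(abca_table("uatgs"))$pos),
       conserved = pick(abca_table("conserved_regions"))[, c("start", "end")],
       rg4 = pick(abca_table("rg4_regions"))[, c("start", "end")])
}
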