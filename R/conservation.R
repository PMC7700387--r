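#' Read a multiple sequence alignment into a character matrix
#'
#' Aligned FASTA and Clustal formats are supported. Sequences are
#' uppercased with U converted to T; `-`, `.` and `~` are treated as gaps
#' and normalised to `-`.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return character matrix (rows = sequences, named by ID).
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
  } else {
    aln <- seqinr::read.alignment(path, format = "clustal")
    ids <- aln$nam
    seqs <- unlist(aln$seq)
  }
  msa_matrix(setNames(seqs, ids))
}

# build/validate an alignment matrix from named aligned strings
msa_matrix <- function(seqs) {
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[.~]", "-", seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0) {
    stop("alignment contains unexpected characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m
}

#' Per-column conservation profile of an ortholog alignment
#'
#' For every alignment column, computes the occupancy (percentage of rows
#' that are not gaps) and the identity (percentage of the modal non-gap
#' residue among non-gap rows; all-gap columns report 0), plus a map from
#' alignment columns to the human sequence's sATG-relative coordinates
#' (NA where the human row is gapped). The human row is taken to be a
#' 5'UTR, so its 3'-most non-gap base maps to -1.
#'
#' @param msa character matrix from [read_msa()] or [msa_matrix()].
#' @param human_row_id rowname of the human (reference) sequence.
#' @return an object of class `conservation_profile`: list with `identity`,
#'   `occupancy` (percent vectors), `column_to_human` (integer vector, NA
#'   for human-gap columns), `n_sequences`, `human_row_id`.
#' @export
profile_alignment <- function(msa, human_row_id) {
  if (!human_row_id %in% rownames(msa)) {
    stop("human row '", human_row_id, "' not found in the alignment",
         call. = FALSE)
  }
  nr <- nrow(msa)
  nongap <- msa != "-"
  occupancy <- 100 * colSums(nongap) / nr
  identity <- apply(msa, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0) return(0)
    100 * max(table(res)) / length(res)
  })
  human <- msa[human_row_id, ]
  hl <- sum(human != "-")
  column_to_human <- rep(NA_integer_, ncol(msa))
  column_to_human[human != "-"] <- linear_to_satg(seq_len(hl) - hl - 1L)
  structure(list(identity = unname(identity), occupancy = unname(occupancy),
                 column_to_human = column_to_human, n_sequences = nr,
                 human_row_id = human_row_id),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("conservation_profile: ", length(x$identity), " columns, ",
      x$n_sequences, " sequences (reference ", x$human_row_id, ")\n", sep = "")
  invisible(x)
}

#' Detect conserved subregions from a conservation profile
#'
#' A conserved subregion is a maximal run of consecutive columns that each
#' pass both the identity and the occupancy cut-off, containing at least
#' `min_run` columns mapped to the human sequence. Regions are reported in
#' human sATG-relative coordinates.
#'
#' @param profile a [profile_alignment()] result.
#' @param identity_cutoff,occupancy_cutoff percent cut-offs (default 80).
#' @param min_run minimum number of human-mapped columns (default 5).
#' @return data.frame with columns `start`, `end`, `n_columns`,
#'   `mean_identity`, `mean_occupancy`.
#' @export
find_conserved_subregions <- function(profile, identity_cutoff = 80,
                                      occupancy_cutoff = 80, min_run = 5L) {
  stopifnot(inherits(profile, "conservation_profile"))
  pass <- profile$identity >= identity_cutoff &
          profile$occupancy >= occupancy_cutoff
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    cols <- starts[k]:ends[k]
    mapped <- profile$column_to_human[cols]
    mapped <- mapped[!is.na(mapped)]
    if (length(mapped) < min_run) next
    out[[length(out) + 1L]] <- data.frame(
      start = min(mapped), end = max(mapped), n_columns = length(mapped),
      mean_identity = mean(profile$identity[cols]),
      mean_occupancy = mean(profile$occupancy[cols]))
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_columns = integer(0), mean_identity = numeric(0),
                      mean_occupancy = numeric(0)))
  }
  do.call(rbind, out)
}

.conservation_groups <- c("primates", "rodents", "other_placental",
                          "sauropsids", "fishes")

# groups required at each category level
.category_requirements <- list(
  `1` = "primates",
  `2` = c("primates", "rodents"),
  `3` = c("primates", "rodents", "other_placental"),
  `4` = c("primates", "rodents", "other_placental", "sauropsids"),
  `5` = c("primates", "rodents", "other_placental", "sauropsids", "fishes"))

#' Conservation category of a uATG across vertebrate subgroups
#'
#' A subgroup "has" the uATG when at least one of its rows shows a gapless
#' A, T, G in the three alignment columns aligned to the human uATG.
#' The category is the highest level whose full requirement is met:
#' 0 human only; 1 primates; 2 primates + rodents; 3 all placental
#' mammals; 4 placental mammals + sauropsids (reptiles and birds);
#' 5 placental mammals + sauropsids + fishes/coelacanth. A presence
#' pattern not matching any nested requirement exactly (e.g. primates and
#' fishes only) is graded at the highest fully satisfied level with a
#' warning.
#'
#' @param msa alignment matrix.
#' @param human_row_id rowname of the human sequence.
#' @param uatg_pos sATG-relative position of the uATG's A in the human
#'   sequence.
#' @param group_labels named character vector mapping each non-human row
#'   to one of `"primates"`, `"rodents"`, `"other_placental"`,
#'   `"sauropsids"`, `"fishes"`.
#' @return integer category 0-5.
#' @export
uatg_conservation_category <- function(msa, human_row_id, uatg_pos,
                                       group_labels) {
  profile_cols <- uatg_columns(msa, human_row_id, uatg_pos)
  others <- setdiff(rownames(msa), human_row_id)
  group_labels <- group_labels[others]
  if (any(is.na(group_labels))) {
    stop("every non-human row needs a group label", call. = FALSE)
  }
  has <- vapply(.conservation_groups, function(g) {
    rows <- others[group_labels == g]
    if (length(rows) == 0) return(FALSE)
    any(vapply(rows, function(r) {
      all(msa[r, profile_cols] == c("A", "T", "G"))
    }, logical(1)))
  }, logical(1))
  category <- 0L
  for (lev in 1:5) {
    if (all(.category_requirements[[as.character(lev)]] %in%
            .conservation_groups[has])) {
      category <- lev
    } else break
  }
  expected <- if (category == 0L) character(0)
              else .category_requirements[[as.character(category)]]
  if (!setequal(.conservation_groups[has], expected)) {
    warning("non-monotone conservation pattern (",
            paste(.conservation_groups[has], collapse = "+"),
            "); graded at category ", category, call. = FALSE)
  }
  category
}

# the three alignment columns of the human uATG; error if the human row is
# gapped there
uatg_columns <- function(msa, human_row_id, uatg_pos) {
  if (!human_row_id %in% rownames(msa)) {
    stop("human row '", human_row_id, "' not found", call. = FALSE)
  }
  human <- msa[human_row_id, ]
  hidx <- which(human != "-")
  hl <- length(hidx)
  p0 <- satg_to_linear(uatg_pos) + hl + 1L  # ungapped index of the A
  if (p0 < 1L || p0 + 2L > hl) {
    stop("uATG at ", uatg_pos, " does not fit in the human row", call. = FALSE)
  }
  cols <- hidx[p0:(p0 + 2L)]
  if (!all(msa[human_row_id, cols] == c("A", "T", "G"))) {
    stop("human row does not carry ATG at position ", uatg_pos, call. = FALSE)
  }
  cols
}
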