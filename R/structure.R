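#' Parse a dot-bracket secondary structure
#'
#' Builds the base-pair list of a pseudoknot-free structure by stack
#' matching. Unbalanced brackets raise an error.
#'
#' @param db dot-bracket string over `(`, `)` and `.`.
#' @param sequence optional nucleotide string of the same length.
#' @return an object of class `secondary_structure`: list with
#'   `dot_bracket`, `sequence`, `pairs` (two-column matrix of 1-based
#'   i < j indices) and `n_pairs`.
#' @examples
#' ss <- parse_dotbracket("((((....))))")
#' ss$n_pairs
#' count_hairpins(ss)
#' @export
parse_dotbracket <- function(db, sequence = NULL) {
  chars <- strsplit(db, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    stop("dot-bracket string may only contain '(', ')' and '.'",
         call. = FALSE)
  }
  if (!is.null(sequence) && nchar(sequence) != length(chars)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) {
        stop("unbalanced dot-bracket string: unmatched ')' at ", i,
             call. = FALSE)
      }
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) {
    stop("unbalanced dot-bracket string: unmatched '(' at ",
         paste(stack, collapse = ", "), call. = FALSE)
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(dot_bracket = db, sequence = sequence, pairs = pairs,
                 n_pairs = nrow(pairs)),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("secondary_structure: ", nchar(x$dot_bracket), " nt, ", x$n_pairs,
      " pairs, ", count_hairpins(x), " hairpin(s)\n", sep = "")
  invisible(x)
}

#' Count hairpin (stem) loops in a secondary structure
#'
#' A hairpin loop is counted for every innermost base pair, i.e. a pair
#' enclosing only unpaired bases. Bulges and internal loops within a stem
#' do not add counts, so one stem-loop arm contributes exactly one.
#'
#' @param ss a [parse_dotbracket()] result (a dot-bracket string is also
#'   accepted).
#' @return integer hairpin count.
#' @export
count_hairpins <- function(ss) {
  if (is.character(ss)) ss <- parse_dotbracket(ss)
  stopifnot(inherits(ss, "secondary_structure"))
  if (ss$n_pairs == 0) return(0L)
  paired <- logical(nchar(ss$dot_bracket))
  paired[as.vector(ss$pairs)] <- TRUE
  sum(vapply(seq_len(nrow(ss$pairs)), function(k) {
    i <- ss$pairs[k, 1]; j <- ss$pairs[k, 2]
    j - i > 1L && !any(paired[(i + 1L):(j - 1L)])
  }, logical(1)))
}

#' Maximum-pairing secondary-structure folder
#'
#' Nussinov-style dynamic programme maximising the number of nested
#' Watson-Crick (optionally plus G:U) base pairs with hairpin loops of at
#' least `min_hairpin` unpaired bases. The traceback is deterministic:
#' when several choices are optimal, position i pairs with the smallest
#' admissible j. This is a desk-scale fallback for thermodynamic folding
#' engines; counts from it are structural upper bounds on pairing, not
#' free-energy predictions.
#'
#' @param seq nucleotide string.
#' @param min_hairpin minimal hairpin-loop size (default 3).
#' @param allow_gu admit G:U wobble pairs (default TRUE).
#' @return a `secondary_structure` (see [parse_dotbracket()]).
#' @export
nussinov_fold <- function(seq, min_hairpin = 3L, allow_gu = TRUE) {
  seq <- normalize_sequence(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  can_pair <- function(a, b) {
    p <- paste0(chars[a], chars[b])
    p %in% c("AT", "TA", "GC", "CG") ||
      (allow_gu && p %in% c("GT", "TG"))
  }
  M <- matrix(0L, n, n)
  if (n > min_hairpin + 1L) {
    for (span in (min_hairpin + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i + 1L, j]
        for (k in (i + min_hairpin + 1L):j) {
          if (can_pair(i, k)) {
            left <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
            right <- if (k + 1L <= j) M[k + 1L, j] else 0L
            best <- max(best, 1L + left + right)
          }
        }
        M[i, j] <- best
      }
    }
  }
  # traceback, preferring to pair i with the smallest admissible k
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i >= j || j - i <= min_hairpin || M[i, j] == 0L) next
    done <- FALSE
    for (k in (i + min_hairpin + 1L):j) {
      if (!can_pair(i, k)) next
      left <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
      right <- if (k + 1L <= j) M[k + 1L, j] else 0L
      if (M[i, j] == 1L + left + right) {
        pairs <- rbind(pairs, c(i, k))
        if (k - 1L > i + 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k + 1L < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        done <- TRUE
        break
      }
    }
    if (!done) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  db <- rep(".", n)
  if (nrow(pairs) > 0) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  out <- parse_dotbracket(paste(db, collapse = ""), sequence = seq)
  out
}

#' Read dot-bracket structure files
#'
#' Accepts the folding-engine output dialect: an optional `>name` header,
#' a sequence line, then a structure line with an optional trailing
#' energy annotation (e.g. `(-12.30)`), which is stripped.
#'
#' @param path text file with one or more records.
#' @return named list of `secondary_structure` objects.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  k <- 1L
  record <- 0L
  while (k <= length(lines)) {
    name <- NULL
    if (startsWith(lines[k], ">")) {
      name <- sub("^>\\s*", "", lines[k])
      name <- sub("\\s.*$", "", name)
      k <- k + 1L
    }
    seq <- trimws(lines[k])
    db <- trimws(lines[k + 1L])
    db <- sub("\\s*\\([-+0-9.]+\\)\\s*$", "", db)
    record <- record + 1L
    if (is.null(name)) name <- paste0("structure_", record)
    out[[name]] <- parse_dotbracket(db, sequence = normalize_sequence(seq))
    k <- k + 2L
  }
  out
}
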