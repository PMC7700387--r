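#' Pairwise distances between aligned sequences
#'
#' The p-distance between two rows is the fraction of mismatches over
#' columns where both rows are non-gap (pairwise deletion). The
#' Jukes-Cantor distance is `-3/4 * log(1 - 4p/3)`; it is undefined for
#' `p >= 0.75`, in which case the distance is capped at `max_distance`
#' with a warning.
#'
#' @param msa character alignment matrix (see [read_msa()]).
#' @param model `"p"` or `"jukes_cantor"`.
#' @param max_distance cap used when the JC transform is undefined.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(msa, model = c("p", "jukes_cantor"),
                              max_distance = 10) {
  model <- match.arg(model)
  n <- nrow(msa)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  capped <- FALSE
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      shared <- msa[a, ] != "-" & msa[b, ] != "-"
      if (!any(shared)) stop("rows ", rownames(msa)[a], " and ",
                             rownames(msa)[b], " share no columns",
                             call. = FALSE)
      p <- mean(msa[a, shared] != msa[b, shared])
      d <- if (model == "p") p else if (p >= 0.75) {
        capped <- TRUE
        max_distance
      } else -0.75 * log(1 - 4 * p / 3)
      D[a, b] <- D[b, a] <- d
    }
  }
  if (capped) warning("Jukes-Cantor undefined for p >= 0.75; ",
                      "distance capped at ", max_distance, call. = FALSE)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a symmetric distance
#' matrix. Taxa are ordered by label before joining so that ties are
#' broken deterministically; negative branch lengths are clamped to zero
#' with a warning.
#'
#' @param D symmetric distance matrix (or `dist`) with taxon labels.
#' @param newick optional path; when given, the tree is also written in
#'   Newick format.
#' @return an \pkg{ape} `phylo` object (unrooted).
#' @export
nj_tree <- function(D, newick = NULL) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix needs taxon labels",
                                 call. = FALSE)
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa",
                        call. = FALSE)
  if (!isTRUE(all.equal(D, t(D)))) stop("distance matrix is not symmetric",
                                        call. = FALSE)
  ord <- order(rownames(D))
  tree <- ape::nj(as.dist(D[ord, ord]))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  if (!is.null(newick)) ape::write.tree(tree, file = newick)
  tree
}
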