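#' Simulate a 5'UTR with planted regulatory features
#'
#' Generates a synthetic spliced 5'UTR carrying exactly the requested
#' features and nothing else: planted uATGs (with a requested context
#' category), closed or sATG-overlapping uORFs, canonical G-quadruplex
#' motifs and hairpin inserts. The background is sampled base by base
#' with rejection so that no accidental ATG (and no G-run of three, which
#' would confound the quadruplex detectors) arises anywhere, and uORF
#' bodies are built from codons free of in-frame stops; standalone uATGs
#' are terminated by a short planted stop so they never seed a reportable
#' uORF. Ground truth is returned alongside the record.
#'
#' @param utr_length 5'UTR length in nt. The default length scale of the
#'   generator family is a few hundred nt, matching typical human 5'UTRs
#'   (median near 212 nt).
#' @param uatgs NULL or data.frame with `pos` (sATG-relative) and
#'   `context` (1-4) for standalone uATGs.
#' @param uorfs NULL or data.frame with `start` (sATG-relative),
#'   `length` (closed uORF length in nt, multiple of 3, stop included)
#'   and `open` (logical; open uORFs run to the sATG without a stop and
#'   ignore `length`).
#' @param g4_sites NULL or integer vector of motif start positions; the
#'   planted motif is `GGGGAGGGGAGGGGAGGGG` (19 nt).
#' @param hairpins NULL or data.frame with `pos` (start), `stem` and
#'   `loop` lengths.
#' @param cds_prefix_length CDS bases appended after the UTR (>= 3 adds
#'   an ATG followed by stop-free codons).
#' @param gene_id,transcript_id identifiers.
#' @param seed optional integer; when given, sets the RNG locally.
#' @return list with `record` (a [utr_record()]) and `truth` (planted
#'   `uatgs`, `uorfs`, `g4`, `hairpins` data.frames plus `dot_bracket`
#'   for the planted hairpins).
#' @export
sim_utr <- function(utr_length = 300L, uatgs = NULL, uorfs = NULL,
                    g4_sites = NULL, hairpins = NULL,
                    cds_prefix_length = 0L, gene_id = "simgene",
                    transcript_id = "simtx", seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  L <- as.integer(utr_length)
  n <- L + as.integer(cds_prefix_length)
  vec <- rep(NA_character_, n)
  planted <- rep(FALSE, n)
  g4_motif <- "GGGGAGGGGAGGGGAGGGG"

  place <- function(idx, chars) {
    if (min(idx) < 1L || max(idx) > n) {
      stop("planted feature does not fit in the sequence", call. = FALSE)
    }
    if (any(planted[idx])) {
      stop("planted features overlap; infeasible packing", call. = FALSE)
    }
    vec[idx] <<- chars
    planted[idx] <<- TRUE
  }
  pos_idx <- function(p) satg_to_index(p, L)

  if (cds_prefix_length >= 3L) {
    place((L + 1L):(L + 3L), c("A", "T", "G"))
    extra <- cds_prefix_length - 3L
    if (extra > 0L) {
      for (k in seq_len(extra %/% 3L)) {
        place(L + 3L * k + 1:3, strsplit(safe_codon(), "")[[1]])
      }
      rem <- extra %% 3L
      if (rem > 0L) {
        start <- L + 3L * (extra %/% 3L) + 3L
        place(start + seq_len(rem), sample(c("A", "C", "T"), rem,
                                           replace = TRUE))
      }
    }
  }

  truth_uorfs <- NULL
  if (!is.null(uorfs)) {
    uorfs <- as.data.frame(uorfs)
    if (is.null(uorfs$open)) uorfs$open <- FALSE
    if (any(uorfs$open) && cds_prefix_length > 0L) {
      stop("open-ended uORFs are only supported without a CDS prefix ",
           "(shifted-frame stops could arise across prefix codons)",
           call. = FALSE)
    }
    rows <- list()
    for (k in seq_len(nrow(uorfs))) {
      s <- uorfs$start[k]
      i <- pos_idx(s)
      if (uorfs$open[k]) {
        n_codon <- (L - i + 1L) %/% 3L
        place(i:(i + 2L), c("A", "T", "G"))
        for (c in seq_len(n_codon - 1L)) {
          place(i + 3L * c + 0:2, strsplit(safe_codon(), "")[[1]])
        }
        rem <- (L - i + 1L) %% 3L
        if (rem > 0L) {
          place((i + 3L * n_codon):(i + 3L * n_codon + rem - 1L),
                sample(c("A", "C"), rem, replace = TRUE))
        }
        rows[[k]] <- data.frame(start = s, end = NA_integer_,
                                open_ended = TRUE,
                                length_nt = 3L * n_codon)
      } else {
        len <- as.integer(uorfs$length[k])
        if (len %% 3L != 0L || len < 9L) {
          stop("closed uORF length must be a multiple of 3 and >= 9",
               call. = FALSE)
        }
        place(i:(i + 2L), c("A", "T", "G"))
        for (c in seq_len(len / 3L - 2L)) {
          place(i + 3L * c + 0:2, strsplit(safe_codon(), "")[[1]])
        }
        place(i + len - 3L + 0:2, c("T", "A", "A"))
        rows[[k]] <- data.frame(start = s,
                                end = index_to_satg(i + len - 1L, L),
                                open_ended = FALSE, length_nt = len)
      }
    }
    truth_uorfs <- do.call(rbind, rows)
  }

  truth_uatgs <- NULL
  all_atg_pos <- integer(0)
  if (!is.null(uatgs)) {
    uatgs <- as.data.frame(uatgs)
    for (k in seq_len(nrow(uatgs))) {
      i <- pos_idx(uatgs$pos[k])
      # short terminated block: ATG + two safe codons + TAA (12 nt < any
      # reportable uORF); strong/optimal contexts need G at +4, which is
      # the first base of the first terminator codon
      codon1 <- if (!is.null(uatgs$context) && uatgs$context[k] >= 3L)
        "GCT" else safe_codon()
      place(i:(i + 2L), c("A", "T", "G"))
      place(i + 3:5, strsplit(codon1, "")[[1]])
      place(i + 6:8, strsplit(safe_codon(), "")[[1]])
      place(i + 9:11, c("T", "A", "A"))
    }
    truth_uatgs <- data.frame(pos = uatgs$pos,
                              context = if (is.null(uatgs$context))
                                NA_integer_ else uatgs$context)
  }

  # contexts: standalone uATGs and uORF starts
  ctx_spec <- rbind(
    if (!is.null(uatgs) && !is.null(uatgs$context))
      data.frame(pos = uatgs$pos, context = uatgs$context),
    if (!is.null(truth_uorfs) && !is.null(uorfs$context))
      data.frame(pos = uorfs$start, context = uorfs$context))
  if (!is.null(ctx_spec) && nrow(ctx_spec) > 0) {
    for (k in seq_len(nrow(ctx_spec))) {
      plant_context(ctx_spec$pos[k], ctx_spec$context[k], pos_idx, place,
                    function() vec, n)
    }
  }

  truth_g4 <- NULL
  if (!is.null(g4_sites)) {
    chars <- strsplit(g4_motif, "")[[1]]
    for (p in g4_sites) {
      i <- pos_idx(p)
      place(i:(i + length(chars) - 1L), chars)
    }
    truth_g4 <- data.frame(start = g4_sites,
                           end = vapply(g4_sites, function(p) {
                             index_to_satg(pos_idx(p) + length(chars) - 1L, L)
                           }, integer(1)))
  }

  truth_hp <- NULL
  db <- rep(".", n)
  if (!is.null(hairpins)) {
    hairpins <- as.data.frame(hairpins)
    for (k in seq_len(nrow(hairpins))) {
      stem <- hairpins$stem[k]; loop <- hairpins$loop[k]
      i <- pos_idx(hairpins$pos[k])
      block <- hairpin_block(stem, loop)
      place(i:(i + 2L * stem + loop - 1L), block)
      db[i:(i + stem - 1L)] <- "("
      db[(i + stem + loop):(i + 2L * stem + loop - 1L)] <- ")"
    }
    truth_hp <- data.frame(pos = hairpins$pos, stem = hairpins$stem,
                           loop = hairpins$loop)
  }

  # background fill with trigram rejection (no ATG, no GGG)
  for (i in which(is.na(vec))) {
    ok <- FALSE
    for (try in 1:50) {
      vec[i] <- sample(c("A", "C", "G", "T"), 1L)
      if (!makes_forbidden_trigram(vec, i, n)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) vec[i] <- "C"  # C occurs in neither ATG nor GGG: always safe
  }

  rec <- utr_record(gene_id, transcript_id, paste(vec, collapse = ""),
                    utr_length = L, cds_prefix_length = cds_prefix_length)
  list(record = rec,
       truth = list(uatgs = truth_uatgs, uorfs = truth_uorfs, g4 = truth_g4,
                    hairpins = truth_hp,
                    dot_bracket = paste(db[1:L], collapse = "")))
}

# a codon containing no stop, no ATG, no GGG and no G at its edges (so
# codon junctions cannot create G-runs or ATGs with neighbours)
.safe_codons <- local({
  bases <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases,
                          paste0))
  keep <- !(all3 %in% c("TAA", "TAG", "TGA", "ATG", "GGG")) &
    !grepl("^G", all3) & !grepl("G$", all3) & !grepl("TA$", all3) &
    !grepl("^TG", all3) & !grepl("AT$", all3) & !grepl("GG", all3)
  all3[keep]
})

safe_codon <- function() sample(.safe_codons, 1L)

# left arm over {A,C} without CCC (revcomp then has no GGG and no ATG)
hairpin_block <- function(stem, loop) {
  repeat {
    arm <- sample(c("A", "C"), stem, replace = TRUE)
    if (!any(grepl("CCC", paste(arm, collapse = "")))) break
  }
  # all-C loop: cannot complete an ATG with either arm, never pairs with
  # the G/T 3' arm, and adds no G-runs
  loop_chars <- rep("C", max(loop, 0L))
  right <- rev(chartr("AC", "TG", arm))
  c(arm, loop_chars, right)
}

plant_context <- function(pos, context, pos_idx, place, get_vec, n) {
  i <- pos_idx(pos)
  vec <- get_vec()
  set_free <- function(idx, chars) {
    free <- is.na(vec[idx])
    if (any(!free)) {
      stop("context planting at ", pos, " collides with another feature",
           call. = FALSE)
    }
    place(idx, chars)
  }
  if (context == 4L) {
    if (i - 6L < 1L) stop("optimal context does not fit at ", pos,
                          call. = FALSE)
    set_free((i - 6L):(i - 1L), c("G", "C", "C", "A", "C", "C"))
    set_p4(i, "G", vec, place, n)
  } else if (context == 3L) {
    set_free(i - 3L, "A")
    set_p4(i, "G", vec, place, n)
  } else if (context == 2L) {
    set_free(i - 3L, "A")
    set_p4(i, "C", vec, place, n)
  } else {
    set_free(i - 3L, "C")
    set_p4(i, "C", vec, place, n)
  }
}

# the +4 base may already be planted (first base of a uORF body codon);
# accept it when compatible, otherwise fail loudly
set_p4 <- function(i, base, vec, place, n) {
  idx <- i + 3L
  if (idx > n) stop("context +4 position outside the sequence", call. = FALSE)
  if (is.na(vec[idx])) {
    place(idx, base)
  } else {
    have <- vec[idx]
    want_g <- base == "G"
    is_g <- have == "G"
    if (want_g != is_g) {
      stop("planted +4 base conflicts with the requested context",
           call. = FALSE)
    }
  }
}

makes_forbidden_trigram <- function(vec, i, n) {
  for (s in max(1L, i - 2L):min(i, n - 2L)) {
    tri <- vec[s:(s + 2L)]
    if (any(is.na(tri))) next
    tri <- paste(tri, collapse = "")
    if (tri == "ATG" || tri == "GGG") return(TRUE)
  }
  FALSE
}

#' Simulate an ortholog alignment with controlled uATG conservation
#'
#' Builds an ungapped alignment of the human 5'UTR and `n_per_group`
#' orthologs per vertebrate subgroup, mutated at per-group substitution
#' rates (defaults grade divergence from primates to fishes). For each
#' uATG a target conservation category dictates in which groups the ATG
#' is preserved intact and in which it is destroyed by a single
#' substitution of the middle base, so the category assigned by
#' [uatg_conservation_category()] is exact by construction.
#'
#' @param record the human [utr_record()].
#' @param uatg_pos sATG-relative positions of the planted uATGs.
#' @param target_categories integer vector (0-5), one per uATG.
#' @param rates named per-site substitution probabilities per group.
#' @param n_per_group orthologs per subgroup (default 2).
#' @param seed optional integer seed.
#' @return list with `msa` (character matrix), `groups` (named vector)
#'   and `categories`.
#' @export
sim_ortholog_msa <- function(record, uatg_pos, target_categories,
                             rates = c(primates = 0.02, rodents = 0.08,
                                       other_placental = 0.12,
                                       sauropsids = 0.22, fishes = 0.32),
                             n_per_group = 2L, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  stopifnot(length(uatg_pos) == length(target_categories))
  human <- strsplit(utr_part(record), "")[[1]]
  L <- record$utr_length
  bases <- c("A", "C", "G", "T")
  rows <- list(human = human)
  groups <- character(0)
  for (g in names(rates)) {
    for (r in seq_len(n_per_group)) {
      s <- human
      mut <- runif(L) < rates[[g]]
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
      for (k in seq_along(uatg_pos)) {
        idx <- satg_to_index(uatg_pos[k], L) + 0:2
        req <- if (target_categories[k] == 0L) character(0)
               else .category_requirements[[as.character(target_categories[k])]]
        if (g %in% req) {
          s[idx] <- c("A", "T", "G")
        } else {
          s[idx] <- c("A", "C", "G")
        }
      }
      nm <- paste0(g, "_", r)
      rows[[nm]] <- s
      groups[nm] <- g
    }
  }
  msa <- do.call(rbind, rows)
  list(msa = msa, groups = groups,
       categories = setNames(as.integer(target_categories),
                             as.character(uatg_pos)))
}

#' Simulate a ribosome-profiling coverage track
#'
#' Poisson counts over the 5'UTR and the first `morf_nt` bases of the
#' main ORF: the mORF region has mean `depth`, the background UTR
#' `background * depth`, and each uORF interval `multiplier * depth`.
#'
#' @param record a [utr_record()].
#' @param uorfs NULL or data.frame with `start`, `end`, `open_ended`.
#' @param depth mean mORF coverage (default 100).
#' @param multipliers uORF occupancy multipliers, recycled per uORF
#'   (default 0.5).
#' @param background UTR background as a fraction of `depth`
#'   (default 0.05).
#' @param morf_nt mORF bases covered (default 90).
#' @param seed optional integer seed.
#' @return a [coverage_track()].
#' @export
sim_coverage <- function(record, uorfs = NULL, depth = 100,
                         multipliers = 0.5, background = 0.05,
                         morf_nt = 90L, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  L <- record$utr_length
  lambda <- c(rep(background * depth, L), rep(depth, morf_nt))
  if (!is.null(uorfs) && nrow(uorfs) > 0) {
    multipliers <- rep_len(multipliers, nrow(uorfs))
    for (k in seq_len(nrow(uorfs))) {
      e <- if (isTRUE(uorfs$open_ended[k]) || is.na(uorfs$end[k])) -1L
           else uorfs$end[k]
      idx <- satg_to_index(uorfs$start[k], L):satg_to_index(e, L)
      lambda[idx] <- multipliers[k] * depth
    }
  }
  coverage_track(record$transcript_id, rpois(length(lambda), lambda), L)
}

#' Simulate variants of known class against planted features
#'
#' Plants one variant per requested class using the record sequence and
#' the planted-feature ground truth: a uORF start disruption, a
#' synonymous and a nonsynonymous SNV at uORF body codons, a 1-nt
#' frameshift insertion inside a uORF, and a featureless background SNV.
#'
#' @param record a [utr_record()].
#' @param truth the `truth` element of [sim_utr()].
#' @param classes which classes to plant.
#' @param seed optional integer seed.
#' @return data.frame with `pos`, `ref`, `alt`, `true_class`.
#' @export
sim_variants <- function(record, truth,
                         classes = c("start_disruption", "synonymous",
                                     "nonsynonymous", "frameshift", "none"),
                         seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  L <- record$utr_length
  uorfs <- truth$uorfs
  if (is.null(uorfs) || nrow(uorfs) == 0) {
    stop("variant simulation needs at least one planted uORF", call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  base_at <- function(i) substr(record$sequence, i, i)
  rows <- list()
  # enumerate body codons (after the start, before the stop) of closed uORFs
  body <- list()
  for (k in seq_len(nrow(uorfs))) {
    i <- satg_to_index(uorfs$start[k], L)
    n_codons <- uorfs$length_nt[k] %/% 3L
    last <- if (uorfs$open_ended[k]) n_codons else n_codons - 1L
    if (last >= 2L) {
      for (c in 2:last) body[[length(body) + 1L]] <- c(k, i + 3L * (c - 1L))
    }
  }
  find_sub <- function(kind) {
    for (b in body) {
      i <- b[2]
      codon <- substr(record$sequence, i, i + 2L)
      for (off in (if (kind == "synonymous") 3L else 1L)) {
        ref <- substr(codon, off, off)
        for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
          alt_codon <- codon
          substr(alt_codon, off, off) <- alt
          eff <- codon_effect(codon, alt_codon)
          if (eff == kind && alt_codon != "ATG") {
            return(data.frame(pos = index_to_satg(i + off - 1L, L),
                              ref = ref, alt = alt, true_class = kind))
          }
        }
      }
    }
    NULL
  }
  for (cl in classes) {
    row <- switch(cl,
      start_disruption = {
        i <- satg_to_index(uorfs$start[1], L)
        data.frame(pos = uorfs$start[1], ref = "A", alt = "G",
                   true_class = "start_disruption")
      },
      synonymous = find_sub("synonymous"),
      nonsynonymous = find_sub("nonsynonymous"),
      frameshift = {
        b <- body[[length(body)]]
        i <- b[2]
        data.frame(pos = index_to_satg(i, L), ref = base_at(i),
                   alt = paste0(base_at(i), "A"), true_class = "frameshift")
      },
      none = {
        occupied <- rep(FALSE, L)
        mark <- function(s, e) {
          idx <- satg_to_index(s, L):satg_to_index(min(e, -1L), L)
          occupied[idx] <<- TRUE
        }
        for (k in seq_len(nrow(uorfs))) {
          mark(uorfs$start[k],
               if (uorfs$open_ended[k]) -1L else uorfs$end[k])
        }
        if (!is.null(truth$uatgs)) for (p in truth$uatgs$pos) {
          mark(p, index_to_satg(satg_to_index(p, L) + 11L, L))
        }
        if (!is.null(truth$g4)) for (k in seq_len(nrow(truth$g4))) {
          mark(truth$g4$start[k], truth$g4$end[k])
        }
        free <- which(!occupied)
        i <- free[ceiling(length(free) / 2)]
        ref <- base_at(i)
        data.frame(pos = index_to_satg(i, L), ref = ref,
                   alt = setdiff(c("A", "C", "T"), ref)[1],
                   true_class = "none")
      })
    if (is.null(row)) {
      stop("could not plant a ", cl, " variant with the given features",
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
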