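#' Find the degenerated segments of a transformation function
#'
#' Degeneration of the genetic code (several codons per amino acid) makes
#' the codon-index to amino-acid-value transformation function
#' non-monotonic. A degenerated segment is a maximal run of consecutive
#' entries (in ascending codon-index order, after removing termination
#' codons) that share one amino-acid value strictly below the running
#' maximum of the values seen before the run. Each segment has a length `L`
#' (codons in the run), a height `H` (running maximum at the run start minus
#' the run's value) and a weight `w = L * H`.
#'
#' Termination codons are removed before scanning: they carry the value 0
#' regardless of their codon index, are excluded from the criterion, and do
#' not break a run. Under the original map `[2 1 3 0]` and the standard code
#' this yields three segments: leucine (L=4, H=4, w=16), serine (L=2, H=12,
#' w=24) and arginine (L=2, H=5, w=10).
#'
#' @param tf A `transformation_function` (or plain integer vector over a
#'   codon-index grid; values 0 are treated as stops).
#' @return A data frame with one row per segment: `amino_acid` (symbol, or
#'   `NA` when `tf` has no provenance), `value`, `L`, `H`, `w`, and `first`
#'   / `last` (codon indices, 0-based, delimiting the run on the original
#'   grid).
#' @export
find_degenerated_segments <- function(tf) {
  v <- as.integer(tf)
  aa <- attr(tf, "amino_acids")
  idx <- seq_along(v) - 1L
  keep <- v != 0L
  v <- v[keep]
  idx <- idx[keep]
  aa <- if (is.null(aa)) rep(NA_character_, length(v)) else aa[keep]

  out <- list()
  runmax <- -Inf
  i <- 1L
  while (i <= length(v)) {
    if (v[i] < runmax) {
      j <- i
      while (j < length(v) && v[j + 1L] == v[i]) j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        amino_acid = aa[i], value = v[i],
        L = j - i + 1L, H = as.integer(runmax - v[i]),
        w = (j - i + 1L) * as.integer(runmax - v[i]),
        first = idx[i], last = idx[j]
      )
      i <- j + 1L
    } else {
      runmax <- max(runmax, v[i])
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(amino_acid = character(0), value = integer(0),
                      L = integer(0), H = integer(0), w = integer(0),
                      first = integer(0), last = integer(0)))
  }
  do.call(rbind, out)
}

#' Weighted-degeneration criterion W
#'
#' The sum of the weights `w = L * H` of all degenerated segments of a
#' transformation function, termination codons excluded. The optimal
#' nucleotide map for a genetic code is the permutation with the lowest W;
#' minimising W minimises the divergence between the codon signal and the
#' translated amino-acid signal.
#'
#' @inheritParams find_degenerated_segments
#' @return Non-negative integer.
#' @examples
#' tf <- transformation_function(original_map(), load_genetic_code(1))
#' weight_criterion_W(tf)  # 16 + 24 + 10 = 50
#' @export
weight_criterion_W <- function(tf) {
  sum(find_degenerated_segments(tf)$w)
}

#' Segment-count criterion N
#'
#' The number of degenerated segments of a transformation function
#' (termination codons excluded) - the earlier, coarser optimality
#' criterion that the weighted criterion W refines.
#'
#' @inheritParams find_degenerated_segments
#' @return Non-negative integer.
#' @export
count_criterion_N <- function(tf) {
  nrow(find_degenerated_segments(tf))
}

#' Score all 24 nucleotide maps against one genetic code
#'
#' @param code A `genetic_code`.
#' @return A data frame in canonical map order with columns `map` (the
#'   `[A C G T]` label), `A`, `C`, `G`, `T`, `W` and `N`. The per-map
#'   segment tables are attached as the `segments` attribute (a list).
#' @export
score_all_maps <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  maps <- enumerate_maps()
  segs <- lapply(maps, function(m) {
    find_degenerated_segments(transformation_function(m, code))
  })
  out <- data.frame(
    map = vapply(maps, format_map, character(1)),
    A = vapply(maps, `[[`, integer(1), "A"),
    C = vapply(maps, `[[`, integer(1), "C"),
    G = vapply(maps, `[[`, integer(1), "G"),
    T = vapply(maps, `[[`, integer(1), "T"),
    W = vapply(segs, function(s) sum(s$w), numeric(1)),
    N = vapply(segs, nrow, integer(1))
  )
  attr(out, "segments") <- segs
  attr(out, "code_id") <- code$id
  out
}

#' Optimal nucleotide map for one genetic code
#'
#' The map(s) attaining the minimal weighted-degeneration criterion W among
#' all 24 permutations. When several maps tie, all are reported and the
#' first in canonical enumeration order is designated primary.
#'
#' @inheritParams score_all_maps
#' @return A list with elements `map` (the primary optimal
#'   `nucleotide_map`), `W`, `N`, `ties` (list of all W-minimal maps) and
#'   `scores` (the full [score_all_maps()] table).
#' @examples
#' optimal_map_for_code(load_genetic_code(1))$map  # [1 0 3 2]
#' @export
optimal_map_for_code <- function(code) {
  scores <- score_all_maps(code)
  best <- which(scores$W == min(scores$W))
  maps <- enumerate_maps()
  if (length(best) > 1L) {
    message("code ", code$id, ": ", length(best),
            " maps tie at W = ", scores$W[best[1]], " (",
            paste(scores$map[best], collapse = ", "),
            "); reporting the first in canonical order as primary")
  }
  list(map = maps[[best[1]]], W = scores$W[best[1]], N = scores$N[best[1]],
       ties = maps[best], scores = scores)
}

#' Suitability ranks and rank-sum scores of all maps across genetic codes
#'
#' Within each genetic code the 24 maps are ranked ascending by W (rank 1 =
#' most suitable); tied W values receive average ranks by default, or
#' competition (minimum) ranks with `ties = "min"`. The suitability score of
#' a map is the sum of its ranks over all codes; using ranks rather than raw
#' W values keeps codes with extreme W from dominating the aggregate.
#'
#' @param codes A list of `genetic_code` objects (e.g. from
#'   [read_genetic_codes()]).
#' @param ties Rank tie policy, `"average"` (default) or `"min"`.
#' @return A list with `scores` (data frame per map: `map` label, `score`,
#'   in canonical order), `ranks` and `W` (24-map x n-code matrices, map
#'   labels as row names and code ids as column names).
#' @export
suitability_scores <- function(codes, ties = c("average", "min")) {
  ties <- match.arg(ties)
  if (length(codes) == 0L) stop("need at least one genetic code")
  stopifnot(all(vapply(codes, inherits, logical(1), "genetic_code")))
  maps <- enumerate_maps()
  labels <- vapply(maps, format_map, character(1))
  W <- vapply(codes, function(cd) score_all_maps(cd)$W,
              numeric(length(maps)))
  W <- matrix(W, nrow = length(maps),
              dimnames = list(labels,
                              vapply(codes, function(x) x$id, integer(1))))
  ranks <- apply(W, 2L, function(w) {
    if (ties == "average") rank(w) else rank(w, ties.method = "min")
  })
  scores <- rowSums(ranks)
  list(scores = data.frame(map = labels, score = unname(scores)),
       ranks = ranks, W = W)
}

#' Globally optimal nucleotide map by suitability rank sum
#'
#' Selects the map with the minimal suitability score over a set of genetic
#' codes (for the packaged 24 NCBI codes: `[1 0 3 2]`, i.e. A=1, C=0, G=3,
#' T=2). Also reports for how many codes the global map is the per-code
#' W-optimum, both as a unique minimizer and counting ties.
#'
#' @inheritParams suitability_scores
#' @return A list: `map` (the global `nucleotide_map`), `score`, `ties`
#'   (maps tying on the score, canonical-order-first is `map`),
#'   `n_codes_unique_optimal` (codes where the global map is the unique
#'   W-minimizer), `n_codes_optimal_with_ties` (codes where it attains the
#'   minimal W, ties included) and `suitability` (the full
#'   [suitability_scores()] result).
#' @export
global_optimal_map <- function(codes, ties = c("average", "min")) {
  suit <- suitability_scores(codes, ties)
  maps <- enumerate_maps()
  best <- which(suit$scores$score == min(suit$scores$score))
  if (length(best) > 1L) {
    message(length(best), " maps tie on the suitability score (",
            paste(suit$scores$map[best], collapse = ", "),
            "); reporting the first in canonical order as primary")
  }
  gmap <- maps[[best[1]]]
  glabel <- format_map(gmap)
  n_unique <- 0L
  n_tied <- 0L
  for (j in seq_len(ncol(suit$W))) {
    w <- suit$W[, j]
    minimizers <- names(w)[w == min(w)]
    if (glabel %in% minimizers) {
      n_tied <- n_tied + 1L
      if (length(minimizers) == 1L) n_unique <- n_unique + 1L
    }
  }
  list(map = gmap, score = suit$scores$score[best[1]], ties = maps[best],
       n_codes_unique_optimal = n_unique,
       n_codes_optimal_with_ties = n_tied,
       suitability = suit)
}
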