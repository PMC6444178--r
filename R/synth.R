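#' Draw biased codon-usage weights
#'
#' Samples per-codon sampling weights from a symmetric Dirichlet
#' distribution over the sense (non-stop) codons of a genetic code;
#' termination codons get weight 0 so generated coding regions are
#' stop-free by construction. Small concentrations give strongly biased
#' usage (a few dominant codons, like the CTA overrepresentation seen in
#' vertebrate mitochondrial data); large concentrations approach uniform
#' usage.
#'
#' @param code A `genetic_code`.
#' @param concentration Positive Dirichlet concentration parameter;
#'   `Inf` gives exactly uniform weights over sense codons.
#' @param seed Optional integer seed.
#' @return A named numeric vector of length 64 (names are codon texts in
#'   T,C,A,G storage order) summing to 1, with 0 at termination codons.
#' @export
biased_usage_weights <- function(code, concentration = 1, seed = NULL) {
  stopifnot(inherits(code, "genetic_code"))
  if (!is.infinite(concentration) && concentration <= 0) {
    stop("concentration must be positive")
  }
  sense <- code$aa != "*"
  w <- numeric(64)
  names(w) <- CODON_STORAGE_ORDER
  if (is.infinite(concentration)) {
    w[sense] <- 1 / sum(sense)
    return(w)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rgamma(sum(sense), shape = concentration, rate = 1)
  if (sum(g) == 0) g <- rep(1, sum(sense))  # numerically degenerate draw
  w[sense] <- g / sum(g)
  w
}

uniform_usage_weights <- function(code) {
  biased_usage_weights(code, Inf)
}

sample_codons <- function(code, n, weights = NULL) {
  if (is.null(weights)) weights <- uniform_usage_weights(code)
  if (length(weights) != 64L) stop("weights must have length 64")
  if (is.null(names(weights))) names(weights) <- CODON_STORAGE_ORDER
  weights[code$aa[names(weights)] == "*"] <- 0
  if (all(weights == 0)) stop("all-zero sampling weights")
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate a random coding sequence
#'
#' Samples `n_codons` sense codons independently with the given usage
#' weights (termination codons are excluded at internal positions), so the
#' result always satisfies the strict encoding preconditions of the
#' generating code: length divisible by 3, no internal stop.
#'
#' @inheritParams biased_usage_weights
#' @param n_codons Number of codons (>= 1).
#' @param weights Usage weights as from [biased_usage_weights()]; `NULL`
#'   for uniform usage over sense codons.
#' @param with_terminal_stop Append one termination codon of the code
#'   (the first in storage order), when the code has any.
#' @return A CDS string.
#' @export
generate_cds <- function(code, n_codons, weights = NULL, seed = NULL,
                         with_terminal_stop = FALSE) {
  if (n_codons < 1L) stop("n_codons must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cod <- sample_codons(code, n_codons, weights)
  cds <- paste(cod, collapse = "")
  if (with_terminal_stop) {
    stops <- names(code$aa)[code$aa == "*"]
    if (length(stops) == 0) {
      warning("code ", code$id, " has no termination codon; none appended")
    } else {
      cds <- paste0(cds, stops[1])
    }
  }
  cds
}

#' Generate a set of random coding sequences
#'
#' @inheritParams generate_cds
#' @param n_seqs Number of sequences.
#' @param prefix Label prefix for sequence names.
#' @return A named character vector of `n_seqs` CDS.
#' @export
generate_cds_set <- function(code, n_seqs, n_codons, weights = NULL,
                             seed = NULL, with_terminal_stop = FALSE,
                             prefix = "seq") {
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(seq_len(n_seqs), function(i) {
    generate_cds(code, n_codons, weights,
                 with_terminal_stop = with_terminal_stop)
  }, character(1))
  names(out) <- paste0(prefix, seq_len(n_seqs))
  out
}

#' Evolve a CDS family down a tree
#'
#' Starting from a root CDS, substitutions are applied along every branch
#' of a rooted topology: the substitution count on a branch is
#' Poisson(`rate` x branch length) and each substitution replaces one
#' randomly chosen codon with a sense codon drawn from the usage weights.
#' Working at the codon level keeps every sequence stop-free and of
#' constant length, so downstream equal-length preconditions hold by
#' construction (a simplification relative to nucleotide-level evolution).
#'
#' @param topology A rooted [ape::phylo] tree with branch lengths; its tip
#'   labels name the output sequences.
#' @param root_cds Root coding sequence, valid under `code`.
#' @param rate Expected substitutions per codon site per unit branch
#'   length, scaled by the sequence length: the Poisson mean on a branch is
#'   `rate * branch_length * n_codons`.
#' @param code A `genetic_code`.
#' @param weights Replacement-codon usage weights (`NULL` = uniform over
#'   sense codons).
#' @param seed Optional integer seed.
#' @return Named character vector of leaf CDS.
#' @export
generate_family <- function(topology, root_cds, rate, code, weights = NULL,
                            seed = NULL) {
  stopifnot(inherits(topology, "phylo"))
  if (!ape::is.rooted(topology)) stop("topology must be rooted")
  if (is.null(topology$edge.length)) stop("topology needs branch lengths")
  root_cds <- normalize_sequence(root_cds)
  cod <- split_codons(root_cds)
  if (any(code$aa[cod] == "*")) {
    stop("root CDS contains stop codons under code ", code$id)
  }
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(topology$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + topology$Nnode)
  seqs[[root]] <- cod
  # parents precede children in a preorder edge walk
  ord <- ape::reorder.phylo(topology, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    s <- seqs[[parent]]
    k <- stats::rpois(1L, rate * ord$edge.length[e] * length(s))
    if (k > 0) {
      pos <- sample.int(length(s), min(k, length(s)))
      s[pos] <- sample_codons(code, length(pos), weights)
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  names(out) <- topology$tip.label
  out
}
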