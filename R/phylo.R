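#' Proportional deviation between two amino-acid signals
#'
#' The phylogenetic distance used for signal-based tree building: the mean
#' absolute difference of the 20-normalized signals,
#' `d = 1/M * sum(|a1[n]/20 - a2[n]/20|)`. The signals must already be of
#' equal length; no alignment is performed.
#'
#' @param a1,a2 Amino-acid-level signals (values 0..20) of equal length
#'   M >= 1.
#' @return Non-negative real.
#' @examples
#' proportional_deviation(c(20, 10), c(10, 10))  # 0.25
#' @export
proportional_deviation <- function(a1, a2) {
  if (length(a1) != length(a2)) {
    stop("signals have different lengths (", length(a1), " vs ",
         length(a2), "); pre-align or trim the sequences")
  }
  if (length(a1) == 0L) stop("empty signals")
  mean(abs(a1 / 20 - a2 / 20))
}

#' Pairwise proportional-deviation distance matrix
#'
#' @param signals Named list of equal-length amino-acid signals (>= 3
#'   taxa, unique labels).
#' @return A symmetric numeric matrix with zero diagonal and the taxon
#'   labels as dimnames.
#' @export
pairwise_distance_matrix <- function(signals) {
  n <- length(signals)
  if (n < 3L) stop("need at least 3 signals")
  labels <- names(signals)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("signals must be named with taxon labels")
  }
  if (anyDuplicated(labels)) {
    stop("duplicated taxon label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  lens <- lengths(signals)
  if (length(unique(lens)) != 1L) {
    off <- labels[lens != stats::median(lens)]
    stop("signals have unequal lengths (offending taxa: ",
         paste(off, collapse = ", "), "); pre-align the sequences")
  }
  dm <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dm[i, j] <- dm[j, i] <- proportional_deviation(signals[[i]],
                                                     signals[[j]])
    }
  }
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]); negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with a message. The result is unrooted unless an outgroup is given.
#'
#' @param dm Symmetric distance matrix with taxon labels (e.g. from
#'   [pairwise_distance_matrix()]).
#' @param outgroup Optional taxon label to root the tree on.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dm, outgroup = NULL) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (all(dm == 0)) warning("all-zero distance matrix: star-like tree")
  tree <- ape::nj(stats::as.dist(dm))
  if (any(tree$edge.length < 0)) {
    message("clamping ", sum(tree$edge.length < 0),
            " negative NJ branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup '", outgroup, "' is not a taxon of the tree")
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}

#' Normalized Robinson-Foulds distance
#'
#' Symmetric-difference count of clades (rooted, the default) or
#' bipartitions (unrooted), divided by its maximum for the leaf count:
#' `2*(n-2)` for two rooted binary trees, `2*(n-3)` for unrooted ones. Two
#' 8-leaf rooted trees differing in exactly one clade are at distance
#' 2/12 ~ 0.167.
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @param rooted Compare clade sets of rooted trees (default) rather than
#'   bipartitions; both trees must then be rooted.
#' @return A number in \[0, 1\].
#' @export
normalized_rf_distance <- function(t1, t2, rooted = TRUE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  n <- length(t1$tip.label)
  if (rooted && (!ape::is.rooted(t1) || !ape::is.rooted(t2))) {
    stop("rooted RF requested but a tree is unrooted; ",
         "root on an outgroup first")
  }
  raw <- phangorn::RF.dist(t1, t2, rooted = rooted, normalize = FALSE)
  denom <- if (rooted) 2 * (n - 2) else 2 * (n - 3)
  if (denom <= 0) stop("too few leaves for a normalized RF distance")
  as.numeric(raw) / denom
}

#' Neighbor-joining tree with bootstrap support from signals
#'
#' Builds the full-data proportional-deviation NJ tree, then resamples the
#' M signal positions with replacement (the same column choice applied to
#' every signal per replicate), rebuilds the tree for each replicate, and
#' labels every internal node of the full-data tree with the percentage of
#' replicates whose tree contains that grouping. Signal-based trees are
#' more sensitive to resampling than symbolic ones, so on the order of 1000
#' replicates is advisable.
#'
#' @inheritParams pairwise_distance_matrix
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed making the resampling reproducible.
#' @param outgroup Optional taxon label; when given, the full tree and all
#'   replicate trees are rooted on it and clades are compared as rooted.
#' @return The full-data [ape::phylo] tree with `node.label` set to
#'   integer-percent supports (the root node label is empty).
#' @export
bootstrap_support <- function(signals, replicates = 1000, seed = NULL,
                              outgroup = NULL) {
  if (length(signals) < 4L) stop("need at least 4 signals")
  if (replicates < 1L) stop("need at least 1 replicate")
  M <- length(signals[[1]])
  full <- nj_tree(pairwise_distance_matrix(signals), outgroup)
  if (!is.null(seed)) set.seed(seed)
  boot <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(M, M, replace = TRUE)
    res <- lapply(signals, function(s) s[cols])
    boot[[r]] <- nj_tree(pairwise_distance_matrix(res), outgroup)
  }
  rooted <- !is.null(outgroup)
  counts <- ape::prop.clades(full, boot, rooted = rooted)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / replicates)
  full$node.label <- as.character(support)
  # the root/basal node grouping is trivially present in every replicate
  full$node.label[1] <- ""
  full
}

#' Signal-based phylogeny from coding sequences
#'
#' Convenience pipeline: encode every CDS as an amino-acid signal under the
#' given map and code (single trailing stops stripped), compute the
#' proportional-deviation distance matrix, build the NJ tree, and
#' optionally root it and attach bootstrap supports.
#'
#' @inheritParams evaluate_map_on_dataset
#' @param outgroup Optional taxon label to root on.
#' @param bootstrap Number of bootstrap replicates; 0 (default) for none.
#' @param seed Seed for the bootstrap resampling.
#' @return A list: `tree` ([ape::phylo]), `distances` (matrix), `signals`.
#' @export
signal_phylogeny <- function(cds_set, code, map, outgroup = NULL,
                             bootstrap = 0, seed = NULL) {
  map <- nucleotide_map(map)
  ids <- names(cds_set)
  if (is.null(ids)) ids <- paste0("seq", seq_along(cds_set))
  signals <- lapply(cds_set, function(s) {
    encode_amino_acids(map, code, s, strip_stops = TRUE)
  })
  names(signals) <- ids
  dm <- pairwise_distance_matrix(signals)
  tree <- if (bootstrap > 0) {
    bootstrap_support(signals, replicates = bootstrap, seed = seed,
                      outgroup = outgroup)
  } else {
    nj_tree(dm, outgroup)
  }
  list(tree = tree, distances = dm, signals = signals)
}
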