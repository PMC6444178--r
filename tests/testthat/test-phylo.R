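std <- load_genetic_code(1)

test_that("proportional deviation follows its formula and is a metric", {
  expect_equal(proportional_deviation(c(3, 5), c(3, 5)), 0)
  expect_equal(proportional_deviation(0, 20), 1)
  expect_equal(proportional_deviation(c(20, 10), c(10, 10)), 0.25)
  expect_error(proportional_deviation(1:3, 1:2), "pre-align")
  set.seed(2)
  for (i in 1:50) {
    a <- sample(0:20, 15, replace = TRUE)
    b <- sample(0:20, 15, replace = TRUE)
    c_ <- sample(0:20, 15, replace = TRUE)
    dab <- proportional_deviation(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, proportional_deviation(b, a))
    expect_lte(proportional_deviation(a, c_),
               dab + proportional_deviation(b, c_) + 1e-12)
  }
})

test_that("distance matrices are symmetric with checked labels", {
  sig <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  dm <- pairwise_distance_matrix(sig)
  expect_true(all(dm == 0))
  set.seed(3)
  sig2 <- list(x = sample(0:20, 9, TRUE), y = sample(0:20, 9, TRUE),
               z = sample(0:20, 9, TRUE))
  dm2 <- pairwise_distance_matrix(sig2)
  expect_equal(dm2, t(dm2))
  expect_equal(dm2["x", "z"],
               proportional_deviation(sig2$x, sig2$z))
  dup <- sig2
  names(dup) <- c("x", "x", "z")
  expect_error(pairwise_distance_matrix(dup), "duplicated")
  uneq <- sig2
  uneq$y <- uneq$y[1:5]
  expect_error(pairwise_distance_matrix(uneq), "unequal")
  expect_error(pairwise_distance_matrix(sig2[1:2]), "at least 3")
})

test_that("NJ reconstructs an additive 4-taxon matrix exactly", {
  # distances from the tree ((A:1,B:2):1,(C:3,D:4))
  lab <- c("A", "B", "C", "D")
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4, dimnames = list(lab, lab))
  tree <- nj_tree(dm)
  # path lengths on the NJ tree reproduce the additive matrix exactly
  expect_equal(as.matrix(stats::cophenetic(tree))[lab, lab], dm)
  # and the AB|CD split is recovered
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(normalized_rf_distance(tree, ref, rooted = FALSE), 0)
})

test_that("normalized rooted RF reproduces 0, 2/12 and 1 on 8 leaves", {
  t1 <- ape::read.tree(text =
    "(((A,B),(C,D)),((E,F),(G,H)));")
  expect_equal(normalized_rf_distance(t1, t1), 0)
  # one clade exchanged: {C,D} replaced by {A,B,C}
  t2 <- ape::read.tree(text =
    "((((A,B),C),D),((E,F),(G,H)));")
  expect_equal(normalized_rf_distance(t1, t2), 2 / 12, tolerance = 1e-12)
  # maximally different rooted caterpillars share no non-trivial clade
  cat1 <- ape::read.tree(text =
    "(((((((A,B),C),D),E),F),G),H);")
  cat2 <- ape::read.tree(text =
    "(((((((H,G),F),E),D),C),B),A);")
  expect_equal(normalized_rf_distance(cat1, cat2), 1)
  expect_equal(normalized_rf_distance(cat2, cat1), 1)
  expect_error(normalized_rf_distance(t1, ape::rtree(5)), "leaf sets")
})

test_that("rooted RF requires rooted trees; unrooted mode does not", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,(E:1,F:1):1);")
  expect_false(ape::is.rooted(tr))
  expect_error(normalized_rf_distance(tr, tr, rooted = TRUE), "unrooted")
  expect_equal(normalized_rf_distance(tr, tr, rooted = FALSE), 0)
})

test_that("bootstrap supports are deterministic and bounded", {
  set.seed(55)
  fam <- generate_family(balanced_8_tree(), generate_cds(std, 60),
                         rate = 0.05, code = std, seed = 55)
  sigs <- lapply(fam, function(s) encode_amino_acids(global_map(), std, s))
  t1 <- bootstrap_support(sigs, replicates = 25, seed = 7)
  t2 <- bootstrap_support(sigs, replicates = 25, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  single <- bootstrap_support(sigs, replicates = 1, seed = 1)
  sup1 <- suppressWarnings(as.numeric(single$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
})

test_that("well-separated clades get near-full bootstrap support", {
  # two tight clades separated by a long internal branch
  fam <- generate_family(ape::read.tree(text = paste0(
    "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):2,",
    "((E:0.05,F:0.05):0.05,(G:0.05,H:0.05):0.05):2);")),
    generate_cds(std, 100), rate = 0.05, code = std, seed = 17)
  sigs <- lapply(fam, function(s) encode_amino_acids(global_map(), std, s))
  bt <- bootstrap_support(sigs, replicates = 200, seed = 17)
  # the deepest split (A-D vs E-H) must be strongly supported
  part <- ape::prop.part(bt)
  labs <- attr(part, "labels")
  sup <- as.numeric(bt$node.label)
  deep <- which(vapply(part, function(p) {
    setequal(labs[p], c("A", "B", "C", "D")) ||
      setequal(labs[p], c("E", "F", "G", "H"))
  }, logical(1)))
  deep <- deep[deep > 1]  # drop the trivial all-taxa node
  expect_true(length(deep) >= 1)
  expect_true(all(sup[deep] >= 95, na.rm = TRUE))
})

test_that("signal phylogeny recovers the generating topology", {
  topo <- balanced_8_tree(0.3)
  fam <- generate_family(topo, generate_cds(std, 148), rate = 0.1,
                         code = std, seed = 99)
  res <- signal_phylogeny(fam, std, global_map())
  expect_equal(normalized_rf_distance(res$tree, topo, rooted = FALSE), 0)
  expect_equal(sort(res$tree$tip.label), sort(names(fam)))
  # rooting on an outgroup yields a rooted tree
  res2 <- signal_phylogeny(fam, std, global_map(), outgroup = "H")
  expect_true(ape::is.rooted(res2$tree))
})
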