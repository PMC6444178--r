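std <- load_genetic_code(1)

test_that("map construction validates permutations and names", {
  m <- nucleotide_map(c(1, 0, 3, 2))
  expect_equal(unclass(m), c(A = 1L, C = 0L, G = 3L, T = 2L))
  expect_equal(format_map(m), "[1 0 3 2]")
  m2 <- nucleotide_map(c(T = 0, C = 1, A = 2, G = 3))
  expect_equal(format_map(m2), "[2 1 3 0]")
  expect_identical(m2, original_map())
  expect_error(nucleotide_map(c(9, 9, 9, 9)), "permutation")
  expect_error(nucleotide_map(c(0, 1, 2)), "4 values")
  expect_error(nucleotide_map(c(X = 0, C = 1, A = 2, G = 3)), "names")
})

test_that("enumerate_maps gives all 24 permutations in canonical order", {
  maps <- enumerate_maps()
  expect_length(maps, 24)
  labels <- vapply(maps, format_map, character(1))
  expect_equal(anyDuplicated(labels), 0)
  expect_equal(labels[1], "[0 1 2 3]")
  expect_equal(labels[24], "[3 2 1 0]")
  expect_true("[2 1 3 0]" %in% labels)  # the original published map
})

test_that("codon_index reads mapped digits as a quaternary number", {
  expect_equal(codon_index(original_map(), "ATG"), 35)
  expect_equal(codon_index(original_map(), "atg"), 35)
  for (m in enumerate_maps()) {
    tttt <- names(unclass(m))[unclass(m) == 0]
    expect_equal(codon_index(m, strrep(tttt, 3)), 0)
    top <- names(unclass(m))[unclass(m) == 3]
    expect_equal(codon_index(m, strrep(top, 3)), 63)
  }
  expect_error(codon_index(original_map(), "ANG"), "untranslatable")
})

test_that("amino-acid values follow first-encounter order (standard code)", {
  aam <- amino_acid_map(original_map(), std)
  expect_equal(unname(aam["F"]), 1)   # TTT first
  expect_equal(unname(aam["L"]), 2)   # TTA before CTN
  expect_equal(unname(aam["M"]), 12)  # 12th newly seen amino acid
  expect_equal(unname(aam["G"]), 20)  # GGN last
  expect_equal(unname(aam["*"]), 0)
})

test_that("amino-acid map invariants hold for all 24 maps x 24 codes", {
  codes <- read_genetic_codes()
  maps <- enumerate_maps()
  for (cd in codes) {
    for (m in maps) {
      aam <- amino_acid_map(m, cd)
      vals <- aam[names(aam) != "*"]
      k <- length(vals)
      expect_true(k <= 20)
      expect_setequal(unname(vals), seq_len(k))
      if ("*" %in% names(aam)) expect_equal(unname(aam["*"]), 0)
    }
  }
})

test_that("the transformation function composes index and value maps", {
  tf <- transformation_function(original_map(), std)
  expect_length(tf, 64)
  expect_equal(as.integer(tf)[1:2], c(1, 1))  # TTT, TTC -> Phe
  expect_equal(as.integer(tf)[11], 0)         # TAA (index 10) -> stop
  expect_equal(max(as.integer(tf)), 20)
  # max entry equals the number of distinct amino acids, every code/map
  for (cd in read_genetic_codes()) {
    k <- length(setdiff(unique(cd$aa), "*"))
    expect_equal(max(as.integer(transformation_function(global_map(), cd))),
                 k)
  }
})

test_that("nucleotide encoding maps bases positionally", {
  expect_equal(encode_nucleotides(nucleotide_map(c(1, 0, 3, 2)), "ACGT"),
               c(1, 0, 3, 2))
  expect_equal(encode_nucleotides(original_map(), "ATG"), c(2, 0, 3))
  expect_equal(encode_nucleotides(original_map(), ""), integer(0))
  expect_error(encode_nucleotides(original_map(), "AXG"), "position 2")
})

test_that("codon encoding is per-triplet and strict on frame", {
  expect_equal(encode_codons(original_map(), "ATG"), 35)
  expect_equal(encode_codons(original_map(), "TTTATG"), c(0, 35))
  expect_error(encode_codons(original_map(), "ATGA"), "divisible by 3")
  expect_warning(
    out <- encode_codons(original_map(), "ATGA", truncate = TRUE),
    "truncating")
  expect_equal(out, 35)
})

test_that("amino-acid encoding composes the transformation function", {
  expect_equal(encode_amino_acids(original_map(), std, "TTTTTC"), c(1, 1))
  expect_equal(encode_amino_acids(original_map(), std, "TAA"), 0)
  expect_equal(encode_amino_acids(original_map(), std, "ATG"), 12)
  expect_equal(encode_amino_acids(original_map(), std, "ATGTAA",
                                  strip_stops = TRUE), 12)
  # pointwise composition identity on random CDS for random maps
  set.seed(42)
  maps <- enumerate_maps()
  for (rep in 1:20) {
    m <- maps[[sample.int(24, 1)]]
    cds <- generate_cds(std, 50)
    tf <- as.integer(transformation_function(m, std))
    c_sig <- encode_codons(m, cds)
    a_sig <- encode_amino_acids(m, std, cds)
    expect_length(a_sig, nchar(cds) / 3)
    expect_equal(a_sig, tf[c_sig + 1])
  }
})

test_that("codon signals of two maps are related by a fixed bijection", {
  all64 <- paste(numap:::CODON_STORAGE_ORDER, collapse = "")
  maps <- enumerate_maps()
  set.seed(7)
  for (rep in 1:5) {
    pair <- sample.int(24, 2)
    s1 <- encode_codons(maps[[pair[1]]], all64)
    s2 <- encode_codons(maps[[pair[2]]], all64)
    expect_setequal(s1, 0:63)
    expect_setequal(s2, 0:63)
    perm <- integer(64)
    perm[s1 + 1] <- s2  # the value-level permutation relating the two maps
    cds <- generate_cds(std, 100)
    expect_equal(perm[encode_codons(maps[[pair[1]]], cds) + 1],
                 encode_codons(maps[[pair[2]]], cds))
  }
})
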