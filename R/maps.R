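#' Construct a nucleotide-integer map
#'
#' A nucleotide map is a bijection from the four bases to the integers 0-3.
#' Maps are written everywhere as the 4-tuple of integers assigned to
#' A, C, G, T in that order, e.g. `[1 0 3 2]` means A=1, C=0, G=3, T=2
#' (the globally optimal map); `[2 1 3 0]` is the original map
#' T=0, C=1, A=2, G=3.
#'
#' @param values Integer vector of length 4: the values for A, C, G, T in
#'   that order (a permutation of 0:3). Names, if present, must be
#'   A, C, G, T in any order and take precedence over position.
#' @return A named integer vector of class `nucleotide_map` with names
#'   `A`, `C`, `G`, `T`.
#' @examples
#' nucleotide_map(c(1, 0, 3, 2))        # the global optimal map
#' nucleotide_map(c(T = 0, C = 1, A = 2, G = 3))
#' @export
nucleotide_map <- function(values) {
  if (inherits(values, "nucleotide_map")) return(values)
  nm <- names(values)
  values <- as.integer(values)
  if (length(values) != 4L) stop("a nucleotide map needs exactly 4 values")
  names(values) <- nm
  if (!is.null(nm)) {
    if (!setequal(nm, c("A", "C", "G", "T"))) {
      stop("nucleotide map names must be A, C, G, T")
    }
    values <- values[c("A", "C", "G", "T")]
  } else {
    names(values) <- c("A", "C", "G", "T")
  }
  if (!setequal(values, 0:3)) {
    stop("nucleotide map values must be a permutation of 0,1,2,3, got [",
         paste(values, collapse = " "), "]")
  }
  structure(values, class = "nucleotide_map")
}

#' @export
print.nucleotide_map <- function(x, ...) {
  cat("Nucleotide map [ACGT] =", format_map(x), "\n")
  invisible(x)
}

#' Format a map as its canonical `[A C G T]` label
#'
#' @param map A `nucleotide_map` (or coercible).
#' @return A string such as `"[1 0 3 2]"`.
#' @export
format_map <- function(map) {
  map <- nucleotide_map(map)
  paste0("[", paste(unclass(map), collapse = " "), "]")
}

#' The previously published optimal map T=0, C=1, A=2, G=3
#' @return A `nucleotide_map`, `[2 1 3 0]` in A,C,G,T order.
#' @export
original_map <- function() nucleotide_map(c(2L, 1L, 3L, 0L))

#' The globally optimal map A=1, C=0, G=3, T=2
#'
#' The map minimising the suitability rank-sum of the weighted-degeneration
#' criterion W over all 24 NCBI genetic codes; see [global_optimal_map()]
#' to recompute it.
#' @return A `nucleotide_map`, `[1 0 3 2]`.
#' @export
global_map <- function() nucleotide_map(c(1L, 0L, 3L, 2L))

#' Enumerate all 24 nucleotide maps
#'
#' @return A list of the 24 (= 4!) `nucleotide_map` permutations in
#'   canonical order: ascending by the tuple of values assigned to
#'   (A, C, G, T), so the first is `[0 1 2 3]` and the last `[3 2 1 0]`.
#' @export
enumerate_maps <- function() {
  perms <- list()
  for (a in 0:3) for (c_ in 0:3) for (g in 0:3) for (t in 0:3) {
    v <- c(a, c_, g, t)
    if (length(unique(v)) == 4L) perms[[length(perms) + 1L]] <- v
  }
  lapply(perms, nucleotide_map)
}

#' Decimal codon index under a nucleotide map
#'
#' Reads the three mapped digits of a codon as a quaternary number:
#' `16*m(b1) + 4*m(b2) + m(b3)`. Under T=0, C=1, A=2, G=3 the codon ATG is
#' 203 in base 4, i.e. index 35.
#'
#' @param map A `nucleotide_map`.
#' @param codon Codon string(s) (A/C/G/T/U, case-insensitive). Vectorized.
#' @return Integer codon index/indices in 0..63.
#' @examples
#' codon_index(original_map(), "ATG")  # 35
#' @export
codon_index <- function(map, codon) {
  map <- nucleotide_map(map)
  codon <- normalize_sequence(codon)
  if (any(nchar(codon) != 3L)) stop("codons must have exactly 3 letters")
  m <- unclass(map)
  digits <- function(i) {
    b <- substr(codon, i, i)
    bad <- !b %in% names(m)
    if (any(bad)) {
      stop("untranslatable codon (ambiguity code?): ",
           paste(unique(codon[bad]), collapse = ", "))
    }
    m[b]
  }
  unname(16L * digits(1L) + 4L * digits(2L) + digits(3L))
}

# Codon texts ordered by ascending codon index under `map`:
# codons_by_index(map)[i + 1] is the codon with index i.
codons_by_index <- function(map) {
  idx <- codon_index(map, CODON_STORAGE_ORDER)
  CODON_STORAGE_ORDER[order(idx)]
}

#' Derive the amino-acid value assignment for a map and code
#'
#' Numerical translation walks the 64 codons in ascending codon-index order
#' under the given map. Termination codons are assigned 0. The first time an
#' amino acid is encountered it receives the next free value, starting at 1;
#' later codons for an already-seen amino acid are skipped. Under the map
#' T=0, C=1, A=2, G=3 and the standard code this yields Phe=1, Leu=2, ...,
#' Gly=20.
#'
#' @inheritParams codon_index
#' @param code A `genetic_code`.
#' @return A named integer vector: amino-acid one-letter codes (plus `"*"`
#'   = 0 when the code has termination codons) to values. Non-stop values
#'   form the contiguous range 1..k where k is the number of distinct amino
#'   acids in the code.
#' @export
amino_acid_map <- function(map, code) {
  stopifnot(inherits(code, "genetic_code"))
  map <- nucleotide_map(map)
  aa_sorted <- unname(code$aa[codons_by_index(map)])
  vals <- integer(0)
  for (a in aa_sorted) {
    if (a != "*" && !a %in% names(vals)) {
      vals[a] <- length(vals[names(vals) != "*"]) + 1L
    }
  }
  if (any(aa_sorted == "*")) vals["*"] <- 0L
  vals
}

#' Build the transformation function of a map and code
#'
#' The transformation function is the length-64 vector mapping codon index
#' (0..63 under the given nucleotide map) to amino-acid value (1..k by
#' first-encounter order; 0 for termination codons). Its non-monotonies are
#' the degenerated segments that the W criterion weighs; see
#' [find_degenerated_segments()].
#'
#' @inheritParams amino_acid_map
#' @return An integer vector of length 64 (class `transformation_function`),
#'   entry `i+1` holding the amino-acid value of the codon with index `i`.
#'   Attributes `map`, `code_id` and `amino_acids` (codon-index-ordered
#'   amino-acid symbols) record the provenance.
#' @examples
#' tf <- transformation_function(original_map(), load_genetic_code(1))
#' tf[1:4]  # TTT,TTC -> Phe = 1; TTA,TTG -> Leu = 2
#' @export
transformation_function <- function(map, code) {
  stopifnot(inherits(code, "genetic_code"))
  map <- nucleotide_map(map)
  aam <- amino_acid_map(map, code)
  aa_sorted <- unname(code$aa[codons_by_index(map)])
  structure(unname(aam[aa_sorted]),
            map = map, code_id = code$id, amino_acids = aa_sorted,
            class = "transformation_function")
}

#' @export
print.transformation_function <- function(x, ...) {
  cat(sprintf("Transformation function: code %d, map %s\n",
              attr(x, "code_id"), format_map(attr(x, "map"))))
  print(as.integer(x))
  invisible(x)
}

split_codons <- function(cds, truncate = FALSE) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    if (!truncate) {
      stop("sequence length ", n, " is not divisible by 3 ",
           "(use truncate = TRUE to drop trailing bases)")
    }
    warning("truncating ", n %% 3L, " trailing base(s)")
    cds <- substr(cds, 1L, n - n %% 3L)
    n <- nchar(cds)
  }
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Encode a sequence as a nucleotide-level signal
#'
#' @inheritParams codon_index
#' @param sequence A nucleotide string (A/C/G/T/U, case-insensitive).
#' @return Integer vector of the mapped digits, same length as the input.
#' @examples
#' encode_nucleotides(original_map(), "ATG")  # 2 0 3
#' @export
encode_nucleotides <- function(map, sequence) {
  map <- nucleotide_map(map)
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) == 0L) return(integer(0))
  b <- strsplit(sequence, "")[[1]]
  bad <- which(!b %in% c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    stop("non-ACGTU character '", b[bad[1]], "' at position ", bad[1])
  }
  unname(unclass(map)[b])
}

#' Encode a CDS as a codon-level signal
#'
#' @inheritParams codon_index
#' @param cds Coding sequence; length must be divisible by 3 unless
#'   `truncate = TRUE`.
#' @param truncate Drop 1-2 trailing bases with a warning instead of
#'   erroring when the length is not a multiple of 3.
#' @return Integer vector of codon indices (0..63), length `nchar(cds)/3`.
#' @examples
#' encode_codons(original_map(), "TTTATG")  # 0 35
#' @export
encode_codons <- function(map, cds, truncate = FALSE) {
  cod <- split_codons(normalize_sequence(cds), truncate)
  if (length(cod) == 0L) return(integer(0))
  codon_index(map, cod)
}

#' Encode a CDS as an amino-acid-level signal
#'
#' Composition of [encode_codons()] with the transformation function:
#' `a[n] = tf[c[n]]`. Termination codons yield 0; a single trailing stop can
#' be removed with `strip_stops` (the terminal stop carries no amino acid
#' and most sequence analyses drop it).
#'
#' @inheritParams encode_codons
#' @param code A `genetic_code`.
#' @param strip_stops Remove one trailing termination codon, if present.
#' @return Integer vector of amino-acid values (0..20).
#' @export
encode_amino_acids <- function(map, code, cds, truncate = FALSE,
                               strip_stops = FALSE) {
  tf <- transformation_function(map, code)
  c_sig <- encode_codons(map, cds, truncate)
  a_sig <- as.integer(tf)[c_sig + 1L]
  if (strip_stops && length(a_sig) > 0 && a_sig[length(a_sig)] == 0L) {
    a_sig <- a_sig[-length(a_sig)]
  }
  a_sig
}
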