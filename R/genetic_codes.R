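# Codons enumerated with base order T, C, A, G at every position; this is the
# fixed storage order of the 64-character assignment strings and is
# independent of any nucleotide-integer map.
CODON_STORAGE_ORDER <- {
  b <- c("T", "C", "A", "G")
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a genetic-code table file
#'
#' Parses a tab-separated table of translation tables, one row per code:
#' `id<TAB>name<TAB>aa_string`, where `aa_string` is the 64-character
#' amino-acid assignment in T,C,A,G codon enumeration order (`'*'` for
#' termination codons). Lines starting with `#` are comments. The packaged
#' file carries the 24 NCBI genetic codes (table numbers 1-6, 9-14, 16,
#' 21-31); a user-supplied file may add or replace codes.
#'
#' @param path Path to the table file. `NULL` (default) reads the packaged
#'   NCBI tables.
#' @return A named list of `genetic_code` objects, names are the code ids.
#' @export
read_genetic_codes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "genetic_codes.tsv", package = "numap",
                        mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("genetic-code table file not found: '", path, "'")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("genetic-code table file '", path, "' contains no records")
  }
  codes <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      stop("malformed row in genetic-code table '", path,
           "' (expected id<TAB>name<TAB>aa_string): ", ln)
    }
    new_genetic_code(as.integer(parts[1]), parts[2], parts[3])
  })
  ids <- vapply(codes, function(x) x$id, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicated genetic-code ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(codes) <- ids
  codes
}

new_genetic_code <- function(id, name, aa_string) {
  if (is.na(id)) stop("genetic-code id must be an integer")
  if (nchar(aa_string) != 64L) {
    stop("amino-acid assignment string for code ", id,
         " has length ", nchar(aa_string), ", expected 64")
  }
  aa <- strsplit(aa_string, "")[[1]]
  bad <- setdiff(unique(aa), c(AMINO_ACIDS, "*"))
  if (length(bad) > 0) {
    stop("invalid amino-acid symbol(s) in code ", id, ": ",
         paste(bad, collapse = ", "))
  }
  names(aa) <- CODON_STORAGE_ORDER
  structure(list(id = as.integer(id), name = name, aa = aa,
                 aa_string = aa_string),
            class = "genetic_code")
}

#' List the available genetic codes
#'
#' @inheritParams read_genetic_codes
#' @return A data frame with columns `id`, `name` and `n_stop` (number of
#'   termination codons). The packaged file yields the 24 NCBI codes;
#'   the retired table numbers 7, 8, 15, 17, 18, 19 and 20 are absent.
#' @export
list_genetic_codes <- function(path = NULL) {
  codes <- read_genetic_codes(path)
  data.frame(
    id = vapply(codes, function(x) x$id, integer(1)),
    name = vapply(codes, function(x) x$name, character(1)),
    n_stop = vapply(codes, function(x) sum(x$aa == "*"), integer(1)),
    row.names = NULL
  )
}

#' Load one genetic code by NCBI table number
#'
#' @param id Integer table number (packaged: one of 1-6, 9-14, 16, 21-31).
#' @inheritParams read_genetic_codes
#' @return A `genetic_code` object: fields `id`, `name`, `aa` (named
#'   character vector over the 64 codons) and `aa_string`.
#' @examples
#' std <- load_genetic_code(1)
#' sum(std$aa == "*")  # 3 stops: TAA, TAG, TGA
#' @export
load_genetic_code <- function(id, path = NULL) {
  codes <- read_genetic_codes(path)
  key <- as.character(as.integer(id))
  if (!key %in% names(codes)) {
    stop("unknown genetic code ", id, "; valid ids: ",
         paste(names(codes), collapse = ", "))
  }
  codes[[key]]
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("Genetic code %d: %s\n", x$id, x$name))
  cat(sprintf("  %d termination codon(s): %s\n", sum(x$aa == "*"),
              paste(names(x$aa)[x$aa == "*"], collapse = " ")))
  invisible(x)
}

# U -> T, case folding; shared boundary normalization for every
# codon/sequence-accepting operation.
normalize_sequence <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Translate a codon symbolically
#'
#' @param code A `genetic_code`.
#' @param codon A 3-letter codon (A/C/G/T; U is accepted and mapped to T;
#'   case-insensitive). Vectorized.
#' @return One-letter amino-acid code(s), `"*"` for termination codons.
#' @examples
#' translate_codon(load_genetic_code(1), "TTT")  # "F"
#' @export
translate_codon <- function(code, codon) {
  stopifnot(inherits(code, "genetic_code"))
  codon <- normalize_sequence(codon)
  if (any(nchar(codon) != 3L)) {
    stop("codons must have exactly 3 letters")
  }
  bad <- !codon %in% CODON_STORAGE_ORDER
  if (any(bad)) {
    stop("untranslatable codon (ambiguity code?): ",
         paste(unique(codon[bad]), collapse = ", "))
  }
  unname(code$aa[codon])
}
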