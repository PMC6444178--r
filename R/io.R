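#' Read coding sequences from a FASTA file
#'
#' @param path Path to a FASTA file (multi-line records allowed; RNA with
#'   U is accepted and normalized later, at encoding time).
#' @return A named character vector of sequences; names are the first
#'   whitespace-delimited token of each header and must be unique. Full
#'   headers are kept in the `description` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: '", path, "'")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("cannot parse FASTA file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("FASTA file '", path, "' has no records")
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicated sequence id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  attr(seqs, "description") <- headers
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for the sequence body.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs))) stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Write signals as a tidy TSV
#'
#' One row per signal position: `id`, `position` (1-based), `value`; the
#' signal level is recorded in a leading `#` comment.
#'
#' @param signals Named list of integer signals.
#' @param path Output path.
#' @param level Signal level recorded in the header comment
#'   ("nucleotide", "codon" or "amino_acid").
#' @export
write_signal_tsv <- function(signals, path, level = "codon") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# level=", level), con)
  writeLines("id\tposition\tvalue", con)
  for (i in seq_along(signals)) {
    s <- signals[[i]]
    if (length(s) > 0) {
      writeLines(paste(names(signals)[i], seq_along(s), s, sep = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Read signals back from a TSV written by [write_signal_tsv()]
#'
#' @param path Path to the TSV.
#' @return Named list of integer signals; attribute `level` holds the
#'   recorded signal level.
#' @export
read_signal_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  first <- readLines(path, n = 1L)
  level <- sub("^# level=", "", first)
  sigs <- lapply(split(df, factor(df$id, levels = unique(df$id))),
                 function(g) as.integer(g$value[order(g$position)]))
  attr(sigs, "level") <- level
  sigs
}

#' Write a distance matrix as TSV
#'
#' @param dm Symmetric labeled matrix.
#' @param path Output path.
#' @param phylip Use PHYLIP square format (leading taxon count line)
#'   instead of a header row of taxa.
#' @export
write_distance_tsv <- function(dm, path, phylip = FALSE) {
  dm <- as.matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  if (phylip) {
    writeLines(as.character(nrow(dm)), con)
    for (i in seq_len(nrow(dm))) {
      writeLines(paste(c(rownames(dm)[i], format(dm[i, ], digits = 10)),
                       collapse = "\t"), con)
    }
  } else {
    writeLines(paste(c("taxon", colnames(dm)), collapse = "\t"), con)
    for (i in seq_len(nrow(dm))) {
      writeLines(paste(c(rownames(dm)[i], format(dm[i, ], digits = 10)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
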