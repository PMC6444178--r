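#' Pearson correlation between two signals
#'
#' Plain product-moment correlation, used to quantify how much of the codon
#' signal's trend survives numerical translation; it is insensitive to the
#' differing value ranges of the two signals.
#'
#' @param c_sig,a_sig Numeric signals of equal length M >= 2.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_corr <- function(c_sig, a_sig) {
  if (length(c_sig) != length(a_sig)) {
    stop("signals have different lengths (", length(c_sig), " vs ",
         length(a_sig), ")")
  }
  if (length(c_sig) < 2L) stop("need at least 2 points for a correlation")
  if (stats::sd(c_sig) == 0 || stats::sd(a_sig) == 0) {
    stop("undefined correlation: constant signal")
  }
  stats::cor(c_sig, a_sig)
}

#' Percentage deviation D between codon and amino-acid signals
#'
#' Both signals are normalized by their maximal possible value (63 for the
#' codon signal, 20 for the amino-acid signal - fixed constants, not
#' per-code maxima) and the mean absolute difference is expressed as a
#' percentage:
#' `D = 100/M * sum(|c[n]/63 - a[n]/20|)`.
#'
#' @param c_sig Codon-level signal (values 0..63).
#' @param a_sig Amino-acid-level signal (values 0..20), same length.
#' @return Non-negative percentage.
#' @examples
#' percentage_deviation(c(63, 0), c(20, 10))  # 25
#' @export
percentage_deviation <- function(c_sig, a_sig) {
  if (length(c_sig) != length(a_sig)) {
    stop("signals have different lengths (", length(c_sig), " vs ",
         length(a_sig), ")")
  }
  if (length(c_sig) == 0L) stop("empty signals")
  mean(abs(c_sig / 63 - a_sig / 20)) * 100
}

#' Evaluate signal distortion of a map over a CDS dataset
#'
#' For every sequence the codon and amino-acid signals are built under the
#' given map and code, and their Pearson correlation and percentage
#' deviation D are computed; the dataset is summarised as mean +/- standard
#' deviation of each metric.
#'
#' @param cds_set Named character vector (or list) of coding sequences.
#' @param code A `genetic_code`.
#' @param map A `nucleotide_map`.
#' @param strip_stops Drop a single trailing termination codon from both
#'   signals before computing metrics (default `TRUE`; the terminal stop is
#'   not part of the protein).
#' @param permissive Log and skip sequences that fail encoding instead of
#'   erroring.
#' @return A list of class `distortion_report`: `per_sequence` (data frame
#'   with `id`, `M`, `corrcoef`, `D`), `mean_corrcoef`, `sd_corrcoef`,
#'   `mean_D`, `sd_D`, `n`, and `skipped` (ids excluded under
#'   `permissive`).
#' @export
evaluate_map_on_dataset <- function(cds_set, code, map, strip_stops = TRUE,
                                    permissive = FALSE) {
  if (length(cds_set) == 0L) stop("empty CDS set")
  map <- nucleotide_map(map)
  ids <- names(cds_set)
  if (is.null(ids)) ids <- paste0("seq", seq_along(cds_set))
  tf <- transformation_function(map, code)
  rows <- list()
  skipped <- character(0)
  for (k in seq_along(cds_set)) {
    res <- tryCatch({
      c_sig <- encode_codons(map, cds_set[[k]])
      a_sig <- as.integer(tf)[c_sig + 1L]
      if (strip_stops && length(a_sig) > 0 &&
          a_sig[length(a_sig)] == 0L) {
        c_sig <- c_sig[-length(c_sig)]
        a_sig <- a_sig[-length(a_sig)]
      }
      if (any(a_sig == 0L)) {
        warning("sequence '", ids[k],
                "' contains internal stop codons (frame error?)")
      }
      data.frame(id = ids[k], M = length(c_sig),
                 corrcoef = pearson_corr(c_sig, a_sig),
                 D = percentage_deviation(c_sig, a_sig))
    }, error = function(e) {
      if (!permissive) stop("sequence '", ids[k], "': ",
                            conditionMessage(e), call. = FALSE)
      message("skipping sequence '", ids[k], "': ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, ids[k]) else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) stop("no sequence could be evaluated")
  per_seq <- do.call(rbind, rows)
  structure(list(
    per_sequence = per_seq,
    mean_corrcoef = mean(per_seq$corrcoef),
    sd_corrcoef = if (nrow(per_seq) > 1L) stats::sd(per_seq$corrcoef) else 0,
    mean_D = mean(per_seq$D),
    sd_D = if (nrow(per_seq) > 1L) stats::sd(per_seq$D) else 0,
    n = nrow(per_seq), skipped = skipped,
    map = map, code_id = code$id
  ), class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf("Signal distortion: code %d, map %s, %d sequence(s)\n",
              x$code_id, format_map(x$map), x$n))
  cat(sprintf("  corrcoef: %.4f +/- %.4f\n", x$mean_corrcoef,
              x$sd_corrcoef))
  cat(sprintf("  D:        %.2f +/- %.2f %%\n", x$mean_D, x$sd_D))
  if (length(x$skipped) > 0) {
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Codon usage of a CDS set
#'
#' Counts every codon over all sequences; codon-usage bias (unequal
#' frequencies of synonymous codons) is the main reason the theoretically
#' optimal map, derived under a uniform-usage assumption, can be beaten on
#' real data.
#'
#' @inheritParams evaluate_map_on_dataset
#' @param truncate Passed to [encode_codons()].
#' @return A data frame of 64 rows in ascending codon-index order under
#'   `map`: `codon`, `index`, `count`, `frequency`. The total codon count
#'   is attached as attribute `total`.
#' @export
codon_usage <- function(cds_set, map, truncate = FALSE) {
  map <- nucleotide_map(map)
  counts <- integer(64)
  for (s in cds_set) {
    idx <- encode_codons(map, s, truncate)
    if (length(idx) > 0) {
      tab <- tabulate(idx + 1L, nbins = 64L)
      counts <- counts + tab
    }
  }
  total <- sum(counts)
  out <- data.frame(
    codon = codons_by_index(map),
    index = 0:63,
    count = counts,
    frequency = if (total > 0) counts / total else rep(0, 64)
  )
  attr(out, "total") <- total
  out
}
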