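# Independent brute-force oracle for degenerated-segment detection.
# Deliberately different implementation: vectorized prefix maximum over the
# stop-stripped vector, per-position dip flags, then merging of adjacent
# equal-valued dip positions.
oracle_segments <- function(tf_values) {
  v <- tf_values[tf_values != 0]
  if (length(v) == 0) return(data.frame(L = integer(0), H = integer(0),
                                        w = integer(0)))
  prefmax <- c(-Inf, cummax(v)[-length(v)])  # max over strictly preceding
  dip <- v < prefmax
  runs <- rle(paste0(dip, "|", v))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- dip[starts]
  data.frame(
    L = runs$lengths[keep],
    H = (prefmax[starts] - v[starts])[keep],
    w = (runs$lengths * (prefmax[starts] - v[starts]))[keep]
  )
}

# Independent per-triplet codon tally used to cross-check codon_usage().
oracle_codon_tally <- function(cds_set, map) {
  counts <- setNames(integer(64), 0:63)
  for (s in cds_set) {
    s <- toupper(s)
    for (i in seq(1, nchar(s), 3)) {
      cod <- substr(s, i, i + 2)
      idx <- as.character(codon_index(map, cod))
      counts[idx] <- counts[idx] + 1L
    }
  }
  unname(counts)
}

balanced_8_tree <- function(bl = 1) {
  ape::read.tree(text = paste0(
    "(((A:", bl, ",B:", bl, "):", bl, ",(C:", bl, ",D:", bl, "):", bl,
    "):", bl, ",((E:", bl, ",F:", bl, "):", bl, ",(G:", bl, ",H:", bl,
    "):", bl, "):", bl, ");"))
}
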