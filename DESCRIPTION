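Package: numap
Title: Degeneration-Reducing Optimal Integer Maps for Genomic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genomic signal processing with the elementary integer
    representation of DNA, where the four nucleotides are mapped to the
    integers 0-3 and coding sequences become quaternary codon signals (0-63)
    and amino-acid signals (0-20). Implements the weighted-degeneration
    criterion W for choosing, among the 24 possible nucleotide-integer
    permutations, the map that minimises the distortion introduced when a
    codon signal is numerically translated to an amino-acid signal, for each
    of the 24 NCBI genetic codes and globally across codes by suitability
    rank sum. Includes signal-distortion metrics (Pearson correlation and
    percentage deviation), codon-usage counting, proportional-deviation
    distances with neighbor-joining tree construction, normalized
    Robinson-Foulds comparison and bootstrap support, and a synthetic
    coding-sequence generator with controllable codon-usage bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
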