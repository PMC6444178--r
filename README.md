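# numap — degeneration-reducing optimal integer maps for genomic signals

Genomic signal processing replaces nucleotide symbols with the integers
0–3, turning a coding sequence into a quaternary **codon signal** (each
triplet read as a base-4 number, 0–63) and, via a numerical analogue of
translation, an **amino-acid signal** (0–20). Because the genetic code is
degenerate, the codon-index → amino-acid-value *transformation function* is
non-monotonic, and how badly the translated signal is distorted depends on
which of the 24 possible nucleotide→integer permutations ("nucleotide
maps") you picked — usually without thinking about it.

`numap` makes that choice explicit. It is for anyone doing signal-domain
sequence analysis (spectral methods, signal alignment, signal-based
phylogenetics) who needs the codon and amino-acid representations of the
same gene to stay as similar as possible, under any of the 24 NCBI genetic
codes.

## The criterion

For a map *m*, codon *b₁b₂b₃* gets index `16·m(b₁) + 4·m(b₂) + m(b₃)`.
Amino acids are numbered 1…20 by first encounter along ascending codon
index (stops are 0). A **degenerated segment** is a maximal run of
consecutive non-stop entries of the transformation function sharing one
value strictly below the running maximum; it has length *L*, height *H*
(running maximum − value) and weight *w = L·H*. The optimization criterion

> **W = Σ w over all degenerated segments (stops excluded)**

is minimised over the 24 maps, per genetic code. A **global map** is chosen
by ranking maps within each code by W and minimising the rank sum over all
24 NCBI codes. Residual distortion is measured by the Pearson correlation
of the two signals and by the percentage deviation
`D = 100/M · Σ |c[n]/63 − a[n]/20|`; equal-length amino-acid signals are
compared by the proportional deviation `d = 1/M · Σ |a₁[n] − a₂[n]|/20`,
which feeds neighbor-joining tree construction with bootstrap support and
normalized Robinson–Foulds comparison.

## Worked example

```r
library(numap)
std <- load_genetic_code(1)          # the standard genetic code

# the historical map T=0, C=1, A=2, G=3, written [A C G T] = [2 1 3 0]
tf <- transformation_function(original_map(), std)
find_degenerated_segments(tf)
#>   amino_acid value L  H  w first last
#> 1          L     2 4  4 16    16   19
#> 2          S     3 2 12 24    44   45
#> 3          R    10 2  5 10    46   47
weight_criterion_W(tf)
#> [1] 50
```

Three amino acids with six-fold degeneracy (Leu, Ser, Arg) each leave a
below-maximum run; their weights 16 + 24 + 10 give W = 50. Scanning all 24
permutations finds a better map:

```r
opt <- optimal_map_for_code(std)
format_map(opt$map); opt$W
#> [1] "[1 0 3 2]"
#> [1] 33
```

`[1 0 3 2]` (A=1, C=0, G=3, T=2) trades three deep segments for seven
shallow ones, cutting W from 50 to 33. The same map wins the rank-sum
aggregation across all 24 genetic codes, and is the unique per-code
optimum for 14 of them:

```r
g <- global_optimal_map(read_genetic_codes())
format_map(g$map); g$score; g$n_codes_unique_optimal
#> [1] "[1 0 3 2]"
#> [1] 58.5
#> [1] 14
```

Encoding a short CDS under the original map:

```r
encode_codons(original_map(), "ATGGTGCTG")       # ATG = 203₄ = 35
#> [1] 35 51 19
encode_amino_acids(original_map(), std, "ATGGTGCTG")  # Met Val Leu
#> [1] 12 16  2
```

A command-line interface (`exec/numap`) wraps the same functions:
`numap optimal --code 2`, `numap distort --code 1 --map global in.fasta`,
`numap phylo --code 1 --map 1,0,3,2 --bootstrap 1000 --seed 7 in.fasta`,
`numap simulate cds --code 1 --n-seqs 50 --len 148 --seed 1 -o out.fasta`.

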