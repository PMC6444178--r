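---
title: "Choosing nucleotide-integer maps that survive numerical translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing nucleotide-integer maps that survive numerical translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numap)
```

## The problem

Genomic signal processing begins by replacing the symbols of a DNA sequence
with numbers. The most elementary representation assigns the four
nucleotides the integers 0–3. It is lossless and convertible: a coding
sequence becomes a *codon signal* by reading each mapped triplet as a
three-digit quaternary number (values 0–63), and a codon signal becomes an
*amino-acid signal* (values 0–20) through a numerical analogue of
translation. Downstream analyses — motif search, spectral analysis,
comparative genomics across the DNA/protein boundary — work best when the
codon signal and its translated amino-acid signal keep the same shape.

They cannot be identical, because the genetic code is degenerate: 64 codons
encode at most 20 amino acids plus termination. The codon-to-amino-acid
value assignment is therefore many-to-one, and the *transformation
function* — the length-64 vector giving each codon index its amino-acid
value — is non-monotonic wherever codons of one amino acid are scattered
across the codon-index axis. How much non-monotony there is depends
entirely on which of the 24 (= 4!) possible nucleotide-to-integer
permutations, here called *nucleotide maps*, was chosen. This package
scores all 24 maps, per genetic code and globally, so that the permutation
is chosen rather than inherited.

## Numerical translation

For a nucleotide map $m$ (e.g. T=0, C=1, A=2, G=3, written `[2 1 3 0]` in
A,C,G,T order), the index of codon $b_1b_2b_3$ is
$16\,m(b_1) + 4\,m(b_2) + m(b_3)$. Amino-acid values are then assigned by a
first-encounter walk: scanning codon indices 0…63 in ascending order, every
termination codon gets 0, and each amino acid gets the next free value
(starting at 1) the first time it appears. Under `[2 1 3 0]` and the
standard code this yields Phe = 1 (TTT is codon 0), Leu = 2 (TTA), …,
Gly = 20. The assignment is recomputed per map and per code; value 0 for
stops is fixed regardless of position, which keeps the sense values
contiguous. For tables in which the reference assignment gives a
conditional stop its amino-acid reading (codes 27, 28, 31) a code may have
fewer than three — possibly zero — stop entries; the walk handles that
uniformly.

## Degenerated segments and the W criterion

Wherever the transformation function drops below the maximum it has already
reached, translated signals are distorted. After deleting stop entries
(they are not part of the protein and are excluded from the criterion), the
function is scanned in ascending codon-index order while tracking the
running maximum of the values seen so far. A *degenerated segment* is a
maximal run of consecutive entries sharing one value strictly below the
running maximum at the run's start. A segment has length $L$ (codons in the
run), height $H$ (running maximum minus the run's value) and weight
$w = L \times H$. Stops neither contribute to nor break runs; two adjacent
runs with different values are distinct segments.

Two criteria summarise a map:

* $N$ — the number of degenerated segments (the historical criterion);
* $W = \sum w$ — the weighted criterion, which also accounts for how many
  codons are displaced and by how far.

Under `[2 1 3 0]` on the standard code there are three segments — leucine
($L=4$, $H=4$, $w=16$; the four CTN codons sit below the running maximum 6
set by tryptophan), serine ($2 \times 12 = 24$) and arginine
($2 \times 5 = 10$) — so $W = 50$, $N = 3$. The per-code optimal map
minimises $W$ over the 24 permutations; for the standard code it is
`[1 0 3 2]` with $W = 33$. $W$ and $N$ can disagree: the W-optimal map
often splits degeneration into more but much shallower segments (for the
standard code, seven segments of weights 1–9 instead of three of weights
10–24), which is exactly the trade the weighted criterion is designed to
make.

## The global map

For sequences without a known genetic code, a single map must work
acceptably everywhere. Raw $W$ values are not comparable across codes
(codes differ in stop counts and degeneracy structure), so maps are ranked
*within* each code by $W$ (rank 1 = lowest), and each map's *suitability
score* is the sum of its ranks over all codes. Rank ties get average ranks
by default; a competition-rank (`ties = "min"`) variant is exposed because
the choice is a convention, and both select the same winner on the packaged
tables. The minimal score over the 24 NCBI codes is attained by
`[1 0 3 2]` (A=1, C=0, G=3, T=2), which is also the unique per-code
$W$-minimizer for 14 of the 24 codes. `global_optimal_map()` reports both
agreement counts — unique minimizers and ties included — since a tie would
make them differ; with the packaged tables the two per-code tie sets (codes
13 and 26) do not involve the global map, so both counts are 14. Where maps
tie (per-code or globally), all are reported and the first in canonical
enumeration order — ascending by the (A,C,G,T) value tuple — is designated
primary.

## Distortion metrics

Residual distortion after translation is quantified per sequence by the
Pearson correlation of the codon and amino-acid signals and by the
percentage deviation

$$D = \frac{100}{M}\sum_{n=1}^{M}\left|\frac{c[n]}{63} -
\frac{a[n]}{20}\right|,$$

where the normalizing constants are the maximal *possible* values of each
representation (63 and 20), not per-code maxima — so $D$ stays comparable
across codes and maps. A single trailing stop codon is stripped by default
before metric computation (it carries no amino acid); internal stops
trigger a warning since they usually indicate a frame error. Dataset
evaluation reports mean ± standard deviation of both metrics.

## Signal phylogenetics

Equal-length amino-acid signals are compared by the proportional deviation
$d = \frac{1}{M}\sum_n |a_1[n] - a_2[n]|/20$, a true metric on signal
space. No alignment is performed — inputs must be pre-aligned or naturally
equal-length. Trees are built by standard Saitou–Nei neighbor joining on
the pairwise $d$ matrix (negative NJ branch lengths are clamped to zero
with a message). Tree agreement is the Robinson–Foulds symmetric difference
normalized by its maximum: clades over $2(n-2)$ for two rooted binary
trees, bipartitions over $2(n-3)$ unrooted; rooted comparison is the
default and requires explicit outgroup rooting — there is no silent
midpoint fallback, because the root placement changes the clade set.

Bootstrap support resamples the $M$ signal positions with replacement (the
same column choice applied to every signal per replicate), rebuilds the
distance matrix and NJ tree per replicate, and labels each internal node of
the full-data tree with the percentage of replicates containing that
grouping. Columns are resampled at the amino-acid-signal level because
those are the signals being compared; resampling nucleotides would scramble
codon frames. Signal-based trees are noticeably more replicate-hungry than
symbolic ones — on the order of 1000 replicates rather than 100 — because a
single substitution can move a signal value by anything from 0 to 19.

## The synthetic-data generator

Real verification collections for most genetic codes are not bundled, so
every behaviour above is exercised on synthetic coding sequences:

* `biased_usage_weights()` draws per-codon sampling weights from a
  symmetric Dirichlet over the sense codons; the concentration parameter
  interpolates between strong codon-usage bias (≪1: a few dominant codons,
  as in vertebrate mitochondrial data) and uniform usage (∞ exactly).
* `generate_cds()` samples codons independently with those weights —
  uniform usage is the assumption under which the W optimum is derived, so
  the W-to-distortion ordering is tested under uniform weights.
* `generate_family()` evolves a root CDS down a rooted tree, with
  Poisson(rate × branch length × codons) codon replacements per branch.

Substitution operates on whole codons, never single nucleotides, so
sequences stay stop-free and of constant length by construction: the strict
encoding preconditions hold without rejection sampling, at the price of
biological realism (no transition/transversion structure, no indels, no
selection). What the generator deliberately does *not* emulate — realistic
substitution models, within-gene usage heterogeneity, alignment error —
bounds what green tests show about real data: they verify the criterion and
the pipelines under the uniform-usage assumption, not the field behaviour
of any particular map, which the distortion module measures on user data.

All randomness flows from per-call `seed` arguments; there is no hidden
global state beyond R's RNG, which each seeded entry point resets.

## Numerical and design choices

* **Frame violations** (length not divisible by 3) are hard errors by
  default; `truncate = TRUE` drops the 1–2 trailing bases with a warning.
  Silent truncation hides annotation errors.
* **Ambiguity codes** (N, R, …) are strict errors in codon-accepting
  operations; dataset evaluation offers `permissive = TRUE` which logs and
  excludes whole sequences, keeping codon/amino-acid signal pairs aligned.
* **U→T and case folding** happen at the boundary of every
  sequence-accepting operation, so RNA input is transparent.
* **Tie-breaks** everywhere are "report all, designate the canonical-order
  first as primary, log the tie" — ties are informative, not noise.
* **Problem sizes.** The test and verification workloads use 50 sequences
  of 148 codons for dataset-level properties (148 codons matches the size
  regime of a typical short vertebrate gene such as beta globin), 1000
  random length-64 vectors for the segment-detector oracle, the full
  24 × 24 map-code grid for exhaustive invariants, and 50 seeds for the
  8-taxon topology-recovery rate. For recovery, the family generator runs
  at substitution rate 0.3 on 0.3-length branches (~13 expected codon
  replacements per branch of a 148-codon CDS): recovery is limited by
  having too *few* changes on internal branches — the rate curve rises from
  ~0.36 at rate 0.03 to a stable plateau ≥ 0.96 from rate 0.2 — and this
  operating point sits mid-plateau at interspecies-scale divergence,
  far from saturation.

## Known limitations

* The W criterion assumes uniform codon usage. Under strong usage bias the
  W-optimal map need not minimise realised distortion — a map that places
  the overrepresented codon of an amino acid close to that amino acid's
  value does better; the codon-usage module exposes the counts needed to
  see this, but no usage-weighted criterion is defined.
* Proportional-deviation phylogenetics requires equal-length, implicitly
  aligned CDS; there is no alignment, no substitution-model correction, and
  no tree search beyond NJ.
* Translation uses basic tables only: no alternative initiation codons, no
  selenocysteine/pyrrolysine, no per-taxon exceptions. For codes with
  conditional stops the primary amino-acid reading is used throughout.
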