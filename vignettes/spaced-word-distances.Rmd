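---
title: "Phylogenetic distances from filtered spaced-word matches"
author: "skimdist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic distances from filtered spaced-word matches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimdist)
```

# The model

`skimdist` estimates the Jukes-Cantor distance between two bacterial
taxa without aligning or assembling anything.  Its unit of evidence is
the *spaced-word match*: given a binary pattern $P$ of length $\ell$
with $w$ *match positions* and $\ell - w$ *don't-care positions*, a
spaced-word match is a pair of length-$\ell$ windows, one from each
sequence set, that agree at every match position of $P$.  Each match
is a gap-free micro-alignment: at the don't-care positions the two
windows may disagree, and those positions are where divergence is
measured.

Matching alone cannot tell homology from chance: with $w = 12$,
random 4.6 Mb-scale sequence pairs produce thousands of background
matches.  Matches are therefore scored at the don't-care positions
with the HOXD-derived nucleotide substitution matrix of Chiaromonte,
Yap and Miller (positive diagonal, transitions penalised less than
transversions; `chiaromonteMatrix()`), and every match with score
$S < T$ is discarded.  At the default $T = 0$ a match scoring exactly
0 is retained.  Homologous windows at moderate divergence score well
above 0 with high probability, while the background score
distribution has mean $\approx -43$ per don't-care position, so the
filter separates the two populations sharply.

Over the retained matches the mismatch frequency is *pooled*,
$$\hat p = \frac{\sum_k m_k}{\sum_k (\ell - w)},$$
not averaged per match: pooling weights every sampled don't-care
position equally and stays well-defined if matches from patterns of
different weight were ever mixed.

Sequencing error is modelled as a uniform substitution channel: each
read base is misread to one of the three other bases with total
probability $e$ (default $e = 0.0024$, the typical Illumina
substitution-error magnitude).  One channel separates a read set from
its genome, so the effective error is $\hat e = e$ for
genome-vs-reads, the composition of two channels
$\hat e = 2e - \tfrac43 e^2$ for reads-vs-reads, and $0$ for
genome-vs-genome.  The channel is inverted exactly under the same
uniform-substitution assumption the Jukes-Cantor model already makes:
$$p = \frac{\hat p - \hat e}{1 - \tfrac43 \hat e},$$
clamped below at 0.  Finally
$$d = -\tfrac34 \ln\!\left(1 - \tfrac43 p\right)$$
converts the corrected mismatch frequency into substitutions per
position.  When no match survives, or $p \ge 3/4$, the estimate is
flagged *undefined* (with the reason recorded) rather than clamped or
reported as infinite — mirroring how such cases must be handled
downstream, where an undefined pair blocks tree building.

## Fragmented comparison of assembled genomes

Whole-genome comparison finds more spaced-word matches per position in
highly similar regions than in diverged ones, so similar regions are
over-represented in the pool and the distance is under-estimated.
`fragmentedDistance()` mitigates this by splitting one genome into
`nFragments` (default 2000) equal-length fragments, estimating a
distance per fragment against the full second genome, and averaging
the defined per-fragment distances with equal weight (undefined
fragments are excluded and counted, not treated as zero).  With core
length $k = \lfloor (G - (\ell-1)) / n \rfloor$, fragment $i$ covers
positions $[ik,\, ik + k + \ell - 2]$ and the last fragment absorbs
the remainder; neighbouring fragments overlap by $\ell - 1$, so every
$\ell$-window of the genome lies in exactly one fragment.  Multi-contig
genomes are fragmented per contig with the fragment budget apportioned
by contig length.

## Trees

`buildDistanceMatrix()` runs the estimator over all taxon pairs,
inferring the comparison mode of each pair from the two roles, and
records undefined pairs as `NA`.  `neighborJoining()` applies
Saitou-Nei Neighbor-Joining (via `ape::nj`), which is exact on
additive matrices; negative branch lengths — classic NJ behaviour on
noisy input — are kept unless `clampNegative = TRUE`.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| pattern | 72/12 seed | `1`/`0` mask; length 72, 12 match positions, 60 don't-care positions |
| threshold $T$ | 0 | don't-care score below which a match is discarded |
| error rate $e$ | 0.0024 | per-base substitution error per read side |
| `nFragments` | 2000 | fragments in the bias-mitigated genome-vs-genome mode |
| read length | 150 bp | simulator: Illumina-like single-end reads |
| coverage | — | simulator: read bases per genome position (e.g. $2^{-6}$) |
| `indelProb` | 0.01 | simulator: per-position indel event probability |
| indel lengths | uniform 1–100 | simulator: event length distribution |

The pattern length 72 suits 150 bp reads: each read contributes
$150 - 72 + 1 = 79$ windows per orientation.  The shipped pattern is a
fixed literal whose layout was chosen once by minimising the seed's
overlap complexity (a Rasbhari-style objective) over random 72/12
masks; shipping a literal keeps every result reproducible, and any
other valid pattern (first position `1`, weight $\le 32$) can be
supplied.  Weight 12 balances sensitivity (the probability that a
homologous window pair agrees at all match positions is
$(1-p)^{12}$) against the background collision rate
($4^{-12}$ per window pair).

# What the simulator emulates — and what it does not

The generators reproduce the benchmark construction the estimator is
designed for: an i.i.d. uniform A/C/G/T genome (`randomGenome()`), a
derived genome at a known Jukes-Cantor distance — each position
substituted with probability $p(d) = \tfrac34(1 - e^{-4d/3})$, so the
ground-truth distance equals `dTrue` under the estimator's own model —
with indel events at 1% of positions, lengths uniform on 1..100 and a
50/50 insertion/deletion split (`evolveGenome()`); and single-end
150 bp reads with uniform start, uniform strand and a uniform 0.24%
substitution-error channel (`simulateReads()`).
`evolveAlongTree()` composes the substitution channel along a known
tree, which keeps expected leaf-to-leaf distances additive.

Real data differ in ways that matter for interpretation:

* **Repeat structure.**  A uniform random genome has no rRNA operons,
  IS elements or other repeat families.  Repeats multiply the number
  of (para)homologous spaced-word matches at a fixed divergence, so
  on real genomes *more* matches survive at the edge of the
  estimability envelope than on the synthetic genomes used here.  The
  envelope measured by the tests and the acceptance script — the
  largest distance at which all 10 replicate read sets yield a
  defined estimate at a given coverage — is therefore conservative:
  at the extreme operating points (coverage $2^{-7}$–$2^{-8}$X near
  the saturation end, or reads-vs-reads at $2^{-6}$X beyond
  $d \approx 0.1$–$0.2$) the expected retained-match count on a
  uniform 4.6 Mb genome is only 1–3, and occasionally a replicate
  finds none.  Passing or failing at those points characterises the
  synthetic conditions, not an implementation property; accuracy in
  the interior of the envelope (see the parameter-recovery results
  below) is unaffected.
* **Error model.**  Real Illumina error is position- and
  context-dependent and includes rare indels; the simulator applies a
  uniform substitution rate only, which is exactly the assumption the
  error correction inverts.
* **Composition.**  No GC bias, codon structure or coverage bias is
  modelled.

# Numerical and design choices

* **Windows containing `N` are skipped entirely** (ambiguity codes are
  normalised to `N` on input): the substitution matrix is defined on
  A/C/G/T only, and scoring `N` as a wildcard would bias the filter.
* **FASTQ qualities are parsed, validated and discarded.**  The error
  model is a global rate, not per-base weighting, so qualities carry
  no information the estimator uses.
* **Strands.**  The second set is matched in forward and
  reverse-complement orientation; each (window pair, strand) is
  counted once.  Reads have unknown orientation, so this is required
  for any read input.  For a genuine self-comparison (the same object
  on both sides) the trivial identity pairs are excluded; distinct
  taxa with identical sequences still match in full.
* **Exact A/B symmetry** of genome-vs-genome estimates holds for
  reversal-symmetric patterns; for asymmetric patterns the
  reverse-strand match sets of $d(A,B)$ and $d(B,A)$ correspond under
  pattern reversal, so the two estimates agree in distribution and to
  high accuracy, but not bit-exactly.
* **Degenerate inputs.**  Empty match sets and saturated frequencies
  yield flagged undefined estimates, never errors; a genome shorter
  than `nFragments` + ℓ refuses to fragment; sequences shorter than ℓ
  contribute no windows.
* **Determinism.**  Every generator takes a seed, derives per-branch
  seeds arithmetically where several streams are needed, and restores
  the caller's RNG state.  Matching is deterministic; `ape::nj`
  resolves Q-criterion ties deterministically, making the whole
  pipeline reproducible end to end.
* **Indel application order.**  All events are drawn against the
  original coordinate system and spliced right-to-left, so
  overlapping events have well-defined semantics; the 50/50
  insertion/deletion split is a symmetry choice and configurable.
* **Two-channel reads-vs-reads correction.**  With reads on both
  sides, two independent error channels compose to
  $\hat e = 2e - \tfrac43 e^2$; this is this package's choice of
  correction for that mode, validated against a Monte-Carlo channel
  simulation in the test suite.

# Problem sizes used by the test suite

The suite verifies the estimator at the benchmark's native scale
where the claim depends on it, and at reduced scale elsewhere: the
estimability envelopes use a 4.6 Mb genome (the size of a typical
*E. coli*-like chromosome) with 10 replicate read sets per operating
point; parameter recovery (true $d \in \{0.05, 0.1, 0.2, 0.4\}$,
coverage 1X, mean over 10 replicates within $\max(10\%, 0.01)$ of the
truth) uses a 1 Mb genome; the 17-taxon tree scenario (a 4-taxon
outgroup clade plus 13 ingroup taxa, one taxon represented only by 1X
reads) uses 0.5 Mb genomes; the fragmented-mode tiling check uses a
50 kb genome with 100 fragments.  Match enumeration is additionally
verified against a brute-force all-window-pairs oracle on 100 random
sequence pairs under 20 random patterns, and Neighbor-Joining against
50 random additive matrices.

# Known limitations

* Only the Jukes-Cantor model is supported (no Kimura 2-parameter or
  rate heterogeneity); distances beyond $\approx 1$ substitution per
  position saturate quickly.
* Single-end reads only; no paired-end awareness, quality trimming or
  SAM/BAM input.
* One pattern per run; no multi-pattern sets or minimizer-style
  acceleration.
* Estimability at the envelope edge depends on the genome's repeat
  content (see above), so envelopes measured on synthetic genomes
  transfer to real genomes only as a lower bound.
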