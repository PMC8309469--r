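---
title: "Promoter box analysis against first-order Markov backgrounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter box analysis against first-order Markov backgrounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterscan)
```

## The question and the model

Degenerate hexamer boxes — the WRKY-bound W-box `(T/C)TGAC(T/C)` and the
bZIP-class ACGT-core boxes (A-box `TACGTA`, T-box `AACGTT`, C-box `GACGTA`,
G-box `CACGTA`) — occur in any genome by chance, and more often in
compositions that favour their letters. `promoterscan` quantifies that
chance with a first-order Markov chain over `{A,C,G,T}`: the first base of a
scanned window is an independent draw from the mononucleotide probabilities
`p(b)`, and each later base depends only on its predecessor through the
conditional dinucleotide probabilities `p(b2 | b1)`. The per-start-position
probability of a hexamer is the product of one mononucleotide and five
transition terms; a degenerate motif's probability sums this over its
expanded exact variants.

Two modelling commitments deserve spelling out, because a printed formula of
the form `pT × pTA × ...` is ambiguous between conditional and joint
dinucleotide frequencies:

* **Conditional reading.** We take `pXY` to mean `p(Y | X)`. A joint
  reading would not define a Markov chain and the resulting "probabilities"
  over all 4096 hexamers would not sum to one. Under the conditional
  reading, normalization is exact, and the test suite verifies it to 1e-12
  against exhaustive enumeration.
* **Start positions.** A window of `L` bp offers `L − k + 1` start positions
  for a `k`-mer, so `expected = p_motif × (L − k + 1)` — 1995 positions for
  the default 2000-bp windows. Linearity of expectation makes this mean
  exact despite overlapping windows; only the *variance* of counts is
  approximated (see calibration below).

### Strand policy and palindromes

Scanning defaults to both strands. Reverse-orientation hits are found by
matching the reverse complement of the pattern on the given sequence, so
positions always refer to the scanned strand. The A- and T-boxes are
reverse-complement palindromes: a forward match implies a reverse match at
the same position, so they are counted **once** per position, both in
scanning and in the probability (no reverse-complement summand). The same
policy is applied to observation and expectation, which keeps the two
commensurable; this matters because a convention mismatch would silently
double or halve enrichment folds. Overlapping occurrences are all counted —
the expectation model counts every start position, so observation must too.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| promoter length | 2000 | bp | the region immediately 5′ of the ATG start codon, 5′UTR included; the standard screening window for these boxes |
| fragment window | 2000 | bp | genome fragments the same width as promoters, so per-window counts are directly comparable |
| GC tolerance | 0.02 | fraction | fragments within ±2% GC of a focal promoter define the GC-stratified background; boundaries closed on both ends |
| max N fraction | 0.1 | fraction | fragments that are >10% N (assembly gaps) are dropped from background estimation |
| strand policy | both | — | boxes act on either strand; palindromes single-counted |
| shared fraction | 0.5 | fraction | a motif is "shared" in a family when at least half the members carry it |

Promoters with less than the requested upstream length are extracted,
flagged `truncated`, and excluded from per-promoter count distributions by
default (their counts are not comparable at fixed length); they remain in
family track tables with their flag. Coordinates are 1-based inclusive on
GFF3 input, 0-based half-open internally and in BED output, and ATG-relative
in human-readable reports (position −1 is the base immediately 5′ of the A).

## Choices where the design was open

* **"Upstream" is relative to the annotated CDS start codon**, not the
  transcription start site, so promoters deliberately include the 5′UTR.
  No TSS inference is attempted.
* **Multiple transcripts:** the first-listed transcript per gene is used.
* **Fragmentation** starts at offset 0 on every contig and discards the
  sub-window remainder; fixed-width windows are required for comparability
  and chromosome ends contribute at most one discarded tail each.
* **GC filter boundaries are inclusive**, so center 0.284 with tolerance
  0.02 retains exactly the GC range 26.4%–30.4%.
* **Windows containing N never match**, and N-containing base pairs are
  excluded from composition counts; adjacent-pair counts never span
  sequence or fragment joins.
* **GC-stratified models** are estimated from the retained fragments
  jointly, each fragment contributing its own within-fragment pairs.
* **Gene-structure skew** is operationalized as `sign(mean − median)` per
  length measure — a deliberately coarse statistic chosen because the
  qualitative claim it supports ("the tail points to longer genes") does
  not warrant a distributional fit. Short single-exon records (<600 bp) are
  flagged as likely partial sequences; they are included in summaries unless
  explicitly excluded, since public ortholog sets include such records.
* **Even-sized medians** are the mean of the two central values.

## What the synthetic generator emulates — and what it does not

The generator produces (i) i.i.d. genomes at a target GC (defaults: 0.36
genome-wide, 0.284 for the promoter-like fixture — AT-rich plant nuclear
composition), (ii) first-order Markov genomes from any composition model,
with `plantlike_composition()` providing a fixed matrix featuring CpG
depletion, mild TpA avoidance and AA/TT enrichment with stationary GC ≈
0.356, and (iii) promoters with motifs planted at known positions and
strands. One global seed expands into per-contig substreams, and planted
words overwrite background bases so coordinates stay stable.

Exact planted-count fixtures need backgrounds free of *chance* occurrences:
at promoter-like GC the expected number of accidental A-boxes in 2000 bp is
about 0.3, so a raw random background would intermittently add hits.
`scrub_motifs()` therefore mutates one base of every unprotected occurrence
and rescans until none remain — a motif-free-background construction, not a
tuning step. The slight GC perturbation this introduces (the demo fixture
lands near 0.26 rather than 0.284) is the accepted cost of exactness.

What the generator does **not** emulate: isochore structure, repeats,
segmental duplications, local GC gradients around genes, and selection on
motif occurrence. Passing tests on synthetic data therefore demonstrate
that the scanning, background estimation and expectation machinery is
internally consistent and correctly calibrated under its own null — not
that any real promoter is enriched. On real genomes the observed/expected
ratio also absorbs whatever higher-order composition structure a first-order
chain cannot capture; this is a property of the method, not a bug of the
implementation.

## Numerical behaviour and verification

The test suite checks, among other things:

* scanning equals a naive every-window-against-every-variant oracle on
  random sequences, and forward hits on a reverse complement map one-to-one
  onto reverse hits under `p → L − k − p`;
* motif probabilities equal brute-force summation over all 4096 hexamers
  (tolerance 1e-12) and hexamer probabilities normalize to 1;
* when every transition row equals the mononucleotide vector the chain
  collapses to the zero-order product;
* over 1000 simulated 2000-bp fragments (2 Mb of generated chain), the mean
  observed count of every box lies within three binomial standard errors of
  its expectation — the binomial variance slightly understates the truth
  for self-overlapping motifs (clumping), which is why the tolerance is
  phrased in standard errors of the mean rather than an absolute band;
* composition estimation on a 1-Mb generated chain recovers all 16
  transition probabilities within ±0.01;
* a planted AtSAG12-like promoter configuration (five A-boxes in the
  ATG-proximal kilobase, two forward and one reverse W-box upstream) is
  re-annotated exactly.

These problem sizes — 1000 fragments, 1-Mb recovery chains, 300–400-bp
oracle sequences — were chosen as the smallest sizes at which the stated
tolerances are statistically comfortable, and they keep the whole suite
around two minutes on a laptop-class single core.

## Known limitations

* Expectations are exact in the mean only; no compound-Poisson or
  overdispersion correction is provided for the *distribution* of counts of
  self-overlapping motifs.
* Degenerate alphabets are limited to `A,C,G,T,Y,R` — sufficient for the
  five boxes; no PWM scoring or mismatch tolerance.
* Ortholog family definitions, alignments and trees are inputs, not
  products: the atlas compares annotations side by side and flags sharing,
  nothing more.
* First-transcript selection is a convention, not a model of isoform
  diversity; genes whose first-listed transcript is atypical will carry its
  structure.
```{r session}
sessionInfo()
```
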