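---
title: "Methods: comparative expression analysis on consensus transcriptomes"
author: "ceact package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative expression analysis on consensus transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Comparing transcript expression between two populations (or closely
related species) is straightforward when both read sets can be mapped to
one shared reference. Without a reference genome, each population gets
its own de novo transcriptome assembly, and the two assemblies are not
directly comparable: homologous transcripts differ in sequence, in
assembled length, and in which parts of the transcript were recovered.
Mapping one population's reads to the other population's assembly
penalizes whichever population is further from the chosen reference.

`ceact` implements a reference-free procedure that removes this
asymmetry. For every homologous transcript pair it isolates the region
the two assemblies actually share — the highest-scoring local-alignment
window — and quantifies both populations on that common ground. The
package also provides the surrounding machinery (quality trimming,
contig filtering, assembly QC, read fragmentation, six-frame ORF
extraction) and a fully synthetic data generator so that the entire
pipeline is testable against known ground truth without any external
data.

## The procedure

1. **Read trimming.** Reads are scanned inward from the 5' and 3' ends,
   removing bases below Q20 until the first base at or above Q20;
   interior low-quality bases are retained. Fully trimmed reads are
   discarded.
2. **Contig filtering.** Assembled transcripts shorter than 200 nt are
   excluded (exactly 200 nt is kept).
3. **Conversion table.** All-vs-all exact Smith–Waterman local alignment
   between the two transcript sets (affine gaps, +1/−2 with gap
   open/extend 5/2 by default, both strands), with Karlin–Altschul
   e-values, `E = m n 2^(−S')` with bit score
   `S' = (λS − ln K)/ln 2`. Hits with `E ≤ 10⁻²⁰` are significant;
   transcripts lacking a significant match are excluded. Pairs are kept
   only when reciprocal-best, so each transcript enters at most one
   pair.
4. **Consensus extraction.** For each pair, the highest-scoring
   alignment window is cut from both members (the contiguous source
   substring spanned by the alignment; minus-strand partners are
   reverse-complemented). This yields two parallel "consensus
   transcriptomes" keyed by pair id.
5. **Fragmentation and four mapping rounds.** Trimmed reads are cut left
   to right into ≤60 nt pieces, keeping a final remainder of ≥40 nt.
   Fragments are mapped ungapped, emulating a Bowtie-1 `-n 1 -5 5 -3 5`
   invocation: 5 nt trimmed from each fragment end, at most one mismatch
   in the first 28 bases, and mismatch Phred qualities summing to at
   most 70. Four rounds are run: A-fragments on the A-consensus and on
   the B-consensus, and B-fragments on the B-consensus and on the
   A-consensus.
6. **Quantification.** Per pair and round,
   `RPKM = 10⁹ · count / (length · total_mapped_in_round)`. Rounds 1–2
   average into the population-A (sGSL-role) RPKM, rounds 3–4 into the
   population-B (Scotian-Shelf-role) RPKM, and
   `FC = log₂(RPKM_B / RPKM_A)`. `FC ≥ 1` is classified down-regulated
   in A, `FC ≤ −1` up-regulated in A (both inclusive), anything between
   unchanged.

Six-frame translation with longest-ORF selection (stop-to-stop, ≥80
amino acids inclusive) is provided as the computational core of the
annotation step; database searches and annotation aggregation are out of
scope.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `q_threshold` | 20 | Phred | end-trimming threshold (1% error) |
| `min_contig_len` | 200 | nt | contig filter; boundary kept |
| match/mismatch | +1/−2 | score | megablast-like nucleotide scheme |
| gap open/extend | 5/2 | cost | affine; gap of length L costs 5+2L |
| `e_cutoff` | 1e−20 | — | conversion-table significance |
| fragment bounds | 40–60 | nt | greedy left-to-right cutting |
| `trim5`/`trim3` | 5/5 | nt | fragment end trimming before mapping |
| `seed_len`, seed mismatches | 28, ≤1 | nt | mapper seed constraint |
| `max_qual_mismatch_sum` | 70 | Phred | mapper quality budget |
| FC thresholds | ±1 | log₂ | inclusive DE classification |

λ and K are not hard-coded: for any match/mismatch scheme with negative
expected score they are solved at construction time — λ by root
bracketing of the identity `Σᵢⱼ pᵢpⱼ exp(λ sᵢⱼ) = 1`, K by the renewal
series of the associated random walk (both tail terms decay
geometrically; the series is truncated at 1e−12). For +1/−2 at uniform
composition this yields λ = 1.3327, K = 0.621, H = 1.124, matching the
standard published values for that scheme.

## What the synthetic generator emulates

`simConfig()` describes a two-population study: ancestral transcripts
drawn i.i.d. at a target GC (default 200 transcripts of 500–1500 nt at
GC 0.5), each lineage mutated independently at `divergence/2`
substitutions and `indelRate/2` indels per site, so homologous pairs
share about `1 − divergence` identity. The default divergence of 0.04
makes essentially all pairs exceed 95% identity, the regime the method
is designed for. Reads are 454-titanium-like: single-end, lengths
~Normal(420, 80) truncated to [40, transcript length], uniform strand,
uniform substitution errors (0.005/base), homopolymer runs of ≥3
identical bases expanding or contracting by one base at 0.005/run (the
dominant 454 error mode), and Phred qualities decaying linearly 38 → 15
with small jitter, so Q20 end-trimming is genuinely exercised.

Reads are sampled with probability proportional to *weight × length*,
which makes RPKM an unbiased estimator of the weight ratio. True
expression ratios are recorded per pair as `log₂(w_B/w_A)`; when an
explicit fold-change design is supplied the weights are split
symmetrically (`w_A = 2^(−fc/2)`, `w_B = 2^(+fc/2)`) around a unit
baseline, otherwise ratios are drawn Normal(0, 1) with a log-normal
per-transcript baseline.

The generator does **not** emulate: chimeric or misassembled contigs,
paralog families (each ancestral transcript yields exactly one homolog
per population), flowgram-level 454 noise, expression-dependent library
biases, or biological replicates. Passing tests therefore demonstrate
correctness of the procedure under the stated error model, not
robustness to assembly artefacts or paralogy in real data.

## Numerical and design choices

- **Reciprocal-best-hit pairing.** One-to-one pairing is required for
  unambiguous per-pair RPKM comparison; best hits in both directions
  must agree, with deterministic tie-breaking (higher raw score, then
  lexicographically smaller partner id). Excluded transcripts are logged
  with a reason (`no_significant_match` / `not_reciprocal_best`).
- **Per-round RPKM length.** Each round normalizes by the length of the
  reference actually mapped in that round (rounds 1 and 4 the A-side
  window, rounds 2 and 3 the B-side window); the two windows can differ
  by indels.
- **Zero handling.** A pair with zero averaged RPKM on either side has
  no defined fold-change and is reported `undefined` rather than forced
  through a pseudocount; an ε-pseudocount on both sides is available as
  an option.
- **Mapper determinism.** Among admissible placements the winner is
  chosen by (fewest mismatches, lowest quality-mismatch sum, smallest
  transcript id, smallest position, + strand) — a total order, so reruns
  are byte-identical; the number of tied placements is reported.
  Multireads are assigned to their single best placement. Candidate
  generation splits the 28 nt seed into two 14 nt blocks; a placement
  with ≤1 seed mismatch leaves one block exact (pigeonhole), so exact
  block lookup enumerates every admissible candidate.
- **N handling.** Sequences are normalized to uppercase A/C/G/T/N on
  read; N never matches anything — in alignment, identity counting, or
  mapping — including another N.
- **ORFs.** Stop-to-stop convention without requiring ATG (sequence ends
  bound runs), standard genetic code with `no.init.codon` semantics (a
  leading CTG is leucine, not an initiator methionine), inclusive 80-aa
  cutoff, N-containing codons translate to X, ties broken by frame
  order +1, +2, +3, −1, −2, −3 then leftmost.
- **Fragment-level remap fraction.** Mapping operates on fragments, so
  the QC remap fraction is fragment-level; the whole-read fraction (a
  read counts if any fragment maps) is emitted alongside.
- **Trimming boundary cases.** A fully low-quality read trims to an
  empty read, which callers drop. An N50 running sum exactly equal to
  half the total counts as reached.

## Validation and problem sizes

The test suite validates each stage against an independent oracle:
Smith–Waterman scores against `Biostrings::pairwiseAlignment` (exact
integer equality, including gapped relatives), the fragment mapper
against an exhaustive `matchPattern`-based placement scan (1000
fragments against a 50 kb reference set, exact agreement of placement
and tie-breaking), longest-ORF extraction against per-codon brute-force
enumeration (1000 random sequences), and N50 against its brute-force
definition.

Method-level guarantees are checked on simulated ground truth at desk
scale, chosen so the whole suite runs in minutes: a fold-change recovery
experiment (200 pairs at 2% divergence, true log₂ ratios cycling through
{−3..3}, 50 000 reads per population so every pair clears 100 mapped
fragments per round; median |FC − truth| ≤ 0.25 and perfect sign
agreement for |truth| ≥ 1), a null control (identical weights,
independent reads; ≤5% of well-covered pairs called DE), homolog recall
(≥99% of 200 true pairs recovered with zero false pairings at 4%
divergence), exact antisymmetry under swapping the population roles, and
an end-to-end null (identical transcriptomes and identical read files
give identity-1 consensus pairs and FC = 0 everywhere defined).

## Limitations

- DE classification is threshold-based only; there is no variance model
  or significance testing (the design has no biological replicates).
- The mapper is ungapped: fragments spanning indels between the
  populations go unmapped, which slightly and symmetrically lowers
  cross-round counts as divergence grows.
- Only the single optimal local alignment per strand is computed; when
  two transcripts share several conserved regions, only the
  highest-scoring window is quantified.
- Paralogy can defeat reciprocal-best pairing in real data; the
  simulator does not model it, so recall figures do not speak to it.
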