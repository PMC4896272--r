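---
title: "bsdbh: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bsdbh: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsdbh)
```

## The problem

Sodium-bisulfite treatment converts unmethylated cytosines to uracil;
after PCR and sequencing they appear as thymines.  In a *directional*
library every fragment derives from one of the two original genomic
strands: fragments from the Watson strand carry a C→T substitution
pattern relative to the forward reference, fragments from the Crick
strand a G→A pattern.  An aligner must treat these substitutions as
free, while still penalizing genuine mismatches, and a caller must then
count, at every genomic cytosine, how many aligned bases support
methylation (unconverted C) versus conversion (T).

## The hash function

All of `bsdbh`'s search machinery is built on a single hash function
mapping `m`-mers to `w`-bit fingerprints (`w ≤ m`).  Each base maps to
one bit — C and T to 0, G and A to 1 — and the fingerprint is the XOR
of the `w`-bit blocks of this bit string: the leading
`ceiling(m/w) − 1` blocks are non-overlapping and taken from the start,
the final block is taken at offset `m − w` and may overlap its
predecessor.  Position 0 of the sequence maps to the most significant
bit, matching the weights `2^(|P|−i−1)` of the integer form of the
encoding.

Three properties follow, and the test suite verifies each exhaustively
at small sizes:

* **bisulfite-aware** — C and T (and G and A) share a bit value, so a
  converted read has exactly the fingerprint of its genomic origin, for
  *any* subset of converted positions, on either strand.  One index
  serves both conversion patterns.
* **de Bruijn** — patterns overlapping by `m − 1` bases have
  fingerprints overlapping by `w − 1` bits, so the hash of a whole text
  is well defined by concatenation and a pattern occurring at text
  position `i` always has its fingerprint at bit `i` of the hashed text
  (no false negatives; false positives are resolved by verification).
* **Hamming-aware** — a base substitution flips at most one bit of the
  encoding, which enters at most two XOR blocks (the final block can
  overlap its predecessor), so patterns at Hamming distance `k` have
  fingerprints within `2k` bit flips.  Candidate fingerprints for a
  search with `k` seed errors are exactly the `2k`-radius Hamming ball
  around the seed fingerprint.  When `w` divides `m` the last block
  does not overlap and each mismatch flips at most *one* fingerprint
  bit; the exhaustive `m = 8, w = 4` sweep in the acceptance suite
  accordingly measures a maximum of 1 flip per mismatch, below the
  guaranteed bound of 2.

## The index

`build_index()` stores, for each of the `2^w` fingerprints, the
ascending list of text positions whose `m`-window hashes to it (a
direct-address CSR table: one offset array of `2^w + 1` entries plus
one position array of `n − m + 1` entries).  Contigs are concatenated
into a single text beforehand; `N` and any other non-ACGT characters
are replaced by random bases under a recorded seed, because the hash
has no symbol for them.  Two consequences, both handled at verification
time rather than indexing time: alignments spanning a contig boundary
of the concatenated text are discarded, and a read can in principle
align to randomized former-N stretches (at desk scale, vanishingly
rare).

The default fingerprint width is `min(32, max(12, ceiling(log2 n) + 2))`
bits — wide enough that the expected bucket load `n / 2^w` stays below
about 1/4, small enough that the bucket table stays desk-scale.  Index
construction rejects `w > 26` (the offset array alone would exceed
256 MiB); the fingerprint functions themselves accept widths up to 32.

## The aligner

For each read the seed is the first `m` bases of the sequence that is
matched against the forward text.  First mates are tried as-is under
the C→T rule and reverse-complemented under the G→A rule; second mates
of a directional pair the other way around (`revcomp` under C→T, as-is
under G→A) — the four combinations are forced by the chemistry of the
directional protocol.  Candidates from the ball lookups are verified
ungapped: at most `k` bisulfite-aware mismatches in the seed, at most
`max_mismatches` over the whole read (default `ceiling(0.05 × length)`;
the upstream tool leaves the full-read budget open).  The bisulfite
rule is asymmetric: genome C under read T is free, genome T under read
C is a mismatch.

The best alignment minimizes the mismatch count.  `status` is
`unique` when exactly one placement attains it; ties give `multiple`
with the leftmost placement (smallest text position, C→T before G→A at
equal position) reported — a fixed tie-break, like the fixed
Hamming-ball enumeration order (flip count, then lexicographic flip
positions, most significant bit first), chosen so repeated runs produce
byte-identical SAM.

**Pairing.**  A pair is *proper* when both mates are uniquely placed on
the same fragment strand (both C→T = Watson, or both G→A = Crick) in FR
orientation with an insert inside `[insert_min, insert_max]` (defaults
100–600 bp; the upstream tool does not publish its defaults).  Note
that in a directional library mates share the *conversion mode* and
differ in *mapping orientation*; any definition under which proper
mates have "opposite modes" is not self-consistent, so the package
defines mode at the fragment level.  When one mate is unique and the
other has tied best placements, the single tie consistent with the
unique mate is promoted (mate rescue, flagged `rescued`); if several
ties are consistent the leftmost is reported but the mate stays
`multiple`.

**Seed placement.**  A single seed at the 5′ end of the matched
sequence.  For reverse-complemented combinations this corresponds to
the 3′ end of the read as sequenced; with quality-independent scoring
(qualities are carried into SAM but never scored) the choice only
matters through sequencing-error position bias, which the uniform-error
simulator does not model.  Multi-seed schemes are out of scope.

## The methylation caller

Genomic Cs and Gs are marked in a bit-vector with rank support
(cumulative counts sampled every 512 bits plus in-block popcounts — the
layout is a package choice; only constant-time rank is required), and
`rank(i)` maps marked positions to a dense counter index space.  Two
blocked counter arrays (primary = C-or-G, converted = T-or-A) hold the
counts bit-packed: blocks of `bl = 256` counters start at 1-bit
capacity and are rebuilt one bit wider whenever a counter would
overflow.  With `bl` at least the read length a counter is incremented
at most once per read, so a block is rebuilt at most once per read and
the total update cost stays linear in the aligned bases; the test suite
asserts both exactness (against plain arrays) and the rebuild bound.

Counting is **gated by conversion mode**: C→T-mode alignments
contribute only at genomic Cs (read C primary, read T converted),
G→A-mode alignments only at genomic Gs.  This is the only reading under
which a directional protocol yields meaningful β values — a
Watson-derived read always shows G at a genomic G, regardless of
methylation, and counting it would drag every reverse-strand β towards
1.  Reads with `multiple` status are excluded by default (discarded
before methylation reconstruction, as is standard); overlapping mates
are both counted (the simplest contract — a `--no-double-count`-style
clip is deliberately not implemented, as fragments at the default
insert sizes do not overlap).

`β = primary / (primary + converted)` is undefined (NA) at zero
coverage; `call_status()` is strict (`β > 0.5`), so β exactly 0.5 —
possible at even coverage — is called unmethylated.  Context
classification uses the standard rule (CpG, CHG, CHH with H ∈ {A,C,T})
on the strand of the cytosine, mirrored through the reverse complement
for genomic Gs; cytosines with fewer than two following bases inside
their contig fall back to CHH and carry a `truncated` flag.

Annotation formats: Bismark-style `cov` (1-based, covered cytosines
only, methylation as a percentage), BED (0-based half-open, all
cytosines), and an EPP-style fixed-column dialect (`contig, pos1,
strand, context, count_primary, coverage, beta`) — the upstream EPP
format is not publicly specified, so the dialect is defined here and
labelled as such.  gzip compression is applied on the fly through a
connection.  Target support: BED intervals are read 0-based half-open,
symmetrically extended by `--extend-targets`, clipped at contig bounds
and merged before use; statistics are the fraction of aligned bases on
target, the mean coverage over target positions, and the mean coverage
at each distance 1..`max_distance` from the nearest target edge
(positions whose true nearest-target distance differs are excluded from
a given distance bin).

## The simulator, and what a green test establishes

`simulate_genome()` draws i.i.d. bases at a target GC fraction (default
0.36, human-like).  `simulate_methylome()` draws an independent
Bernoulli state per cytosine per strand — CpG rate 0.8, non-CpG rate
0.05 by default, typical of mammalian methylomes; binary states (not
continuous levels) are used so that "correctly called" is decidable
under the strict β > 0.5 rule.  `simulate_reads()` draws fragments
uniformly (per contig, by length), assigns Watson/Crick with equal
probability, normally distributed insert sizes (default 300 ± 50,
clipped to the read length),
converts each unmethylated cytosine of the fragment strand with
probability 0.98 (the typical bisulfite conversion efficiency;
methylated cytosines never convert), and applies uniform substitution
errors (default 1%) afterwards.  Read origins are encoded in read
names and returned as a truth table.

The generator intentionally does **not** model: indels or structural
variants (the aligner is ungapped), SNPs, quality-dependent or
position-dependent error profiles, PCR duplicates, coverage bias,
repeat structure of real genomes, or partial/continuous methylation.
A green accuracy test therefore establishes that the index, search,
counting and scoring machinery is correct under the stated noise model
— not that the tool matches any particular behaviour on real libraries
with indels and repeats.  Mate conversion draws are independent, so a
fragment shorter than twice the read length can show inconsistent
conversion in the mate-overlap region; at the default insert geometry
such fragments are rare.

## Evaluation rules

Mapping: only unique alignments are judged; an alignment is correct iff
contig and conversion mode match the truth and the leftmost position is
within 50 bases (a tolerance that, upstream, absorbs indels and
clipping; here the aligner is ungapped, so observed errors are either 0
or large).  Methylation: only cytosines at coverage ≥ 3 enter the
accuracy denominator; the call is the strict β > 0.5 rule against the
binary truth.

## Degenerate inputs and numerical choices

* `m < w` is rejected at parameter construction (the hash requires
  `w ≤ m`); reads shorter than `m` are reported unmapped with a
  warning.
* Fingerprints are carried in R as doubles (exact for `w ≤ 32`);
  all bit manipulation happens in C++ on unsigned integers.
* Reads containing `N` are alignable — `N` never matches, and the
  fingerprint treats it as bit 0; a seed `N` therefore consumes part of
  the error budget and may push a read past `k`, which errs on the
  side of unmapped rather than misplaced.
* The index container is little-endian binary with a magic number and
  version; loads verify both and fail loudly on truncation.
* All randomness (N-randomization, simulation) flows through named
  integer seeds, and every function restores the caller's RNG state.

## Known limitations

Gapped alignment, quality trimming, non-directional/PBAT protocols,
BAM output, bzip2 compression and external-memory operation are out of
scope.  The index stores plain R integer vectors rather than a
bit-level succinct layout: the data-structure *semantics* (bucket
contents, rank answers, counter values) are the fidelity target, not
the bit-level footprint of the original implementation.  `--threads`
is accepted for interface parity but execution is serial.
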