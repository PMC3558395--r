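---
title: "Collision statistics for hashed chemical identifiers"
author: "inchikeystats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collision statistics for hashed chemical identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inchikeystats)
```

## The problem

The InChIKey is the 27-character hashed companion of the InChI, built for
indexing and exact-match searching: a 14-letter first block encoding the
molecular skeleton, an 8-letter second block encoding stereo, isotopic and
(for non-standard keys) tautomeric layers, two flag letters, and a
protonation letter.  Each block is a truncation of the SHA-256 digest of
the corresponding part of the InChI string — 65 leading bits for the first
block, 37 for the second — re-expressed in capital letters.

Hashing an unbounded structure space into 2^65 (or 2^37) values makes
collisions — two distinct structures sharing a block — unavoidable.  The
design question is quantitative: does the *frequency* of collisions match
what an ideally uniform hash would produce?  If it does, the key delivers
the best collision resistance its width permits.  This package implements
the three ingredients needed to ask and answer that question: the
closed-form theory, an explicit model of the letter layout, and synthetic
key-production machinery with collision-counting and letter-statistics
experiments on top.

## The birthday model

With `k` inputs hashed uniformly onto `p` values, each of the
$\binom{k}{2}$ input pairs collides with probability $1/p$, so the
expected number of same-hash pairs is

$$D(k) = \frac{k(k-1)}{2p}.$$

`expectedCollisions()` evaluates this; `collisionProbability()` gives the
probability that at least one collision occurs,
$1 - \prod_{i=1}^{k-1}(1 - i/p)$, switching to the Poisson-regime form
$1 - e^{-D(k)}$ above $k = 10^6$ (the exact product is $O(k)$; at that
size the two agree to well below $10^{-6}$ relative, which the test suite
asserts).  Two dataset-size thresholds summarize a hash space:

* `halfProbabilityThreshold()` — smallest `k` whose collision probability
  reaches 1/2, i.e. $k \ge (1 + \sqrt{1 + 8\ln 2\,p})/2$.  For `p` = 365
  this is the classic 23 birthdays; for the 37- and 65-bit blocks it is
  436,499 and 7,151,589,655.
* `halfExpectationThreshold()` — smallest `k` with $D(k) \ge 1/2$,
  i.e. $k(k-1) \ge p$: 370,729 for 37 bits and about $6.1 \times 10^9$
  for 65 bits, the sizes quoted as the two blocks' collision resistance.

```{r thresholds}
halfProbabilityThreshold(birthdayModel(bits = 65))
halfExpectationThreshold(birthdayModel(bits = 37))
expectedCollisions(1e6, birthdayModel(bits = 37))
```

### Numerical choices

No arbitrary-precision library is required.  `p` is stored as a double —
powers of two up to $2^{1023}$ are represented exactly — and $D(k)$ is
computed as `(k/2) * ((k-1)/p)`, which is accurate to 15–16 significant
digits, far beyond the 4–5 digits ever reported.  The thresholds, by
contrast, must be *exactly* the right integer, and near $k \approx 7
\times 10^9$ the product $k(k-1)$ occupies 66 bits, past what a double
holds.  Both threshold conditions reduce to $k(k-1) \ge t$; the boundary
comparison is done with Dekker's error-free two-product, which represents
$k(k-1)$ exactly as an unevaluated sum of two doubles.  The floating-point
root is then adjusted by exact comparisons, so the returned integer is
never off by one.  (One consequence, fixed by exact arithmetic: the
37-bit half-expectation threshold is 370,729, since
$370{,}728 \times 370{,}727 = 137{,}438{,}879{,}256$ falls just short of
$2^{37} = 137{,}438{,}953{,}472$.)

The parenthesization of the half-probability bound is pinned by its known
values (23; 436,499; 7,151,589,655): the radicand is $1 + 8\ln 2\,p$ and
the whole expression is halved.  Renderings of the formula elsewhere are
typographically ambiguous; the values are not.

## The letter layout as codecs

A block is a concatenation of 3-letter units ("triplets") and one final
2-letter unit ("doublet"), and not every letter combination is a valid
unit: the valid triplets are AAA..ZZZ minus the ranges EAA..EZZ and
TAA..TTV (17,576 − 676 − 516 = 16,384 = 2^14), and the valid doublets are
AA..TR (19 × 26 + 18 = 512 = 2^9).  Hence no triplet opens with 'E', only
TTW..TZZ open with 'T', and no doublet opens with U..Z — which is exactly
why those letters are depleted (or absent) at specific positions of
observed keys, and why a 14-letter block has $16{,}384^4 \times 512 =
2^{65}$ valid values even though $26^{14} > 2^{65}$ strings exist.

`tripletCodec()` and `doubletCodec()` materialize the unit tables;
`block1Layout()` and `block2Layout()` assemble them.  `encodeBlock()` /
`decodeBlock()` implement the mixed-radix bijection between integers and
blocks, and `parseKey()` validates full 27-character keys.

Two conventions here are *emulation choices*, not claims about the
official software's internals, which a black-box statistical analysis
cannot pin down: (i) the leading digest bits feed the leading unit
(most-significant-first mixed radix); (ii) flag letters default to "SA"
and protonation to "N".  Every statistic this package studies — collision
counts, letter frequencies, sequence probabilities — is invariant to the
bit-assignment order and to which 65/37 of the 256 digest bits are kept,
because a uniform bit string is uniform under any fixed selection and
permutation.

Since block values reach $2^{65}-1$, values above $2^{53}$ are passed and
returned as decimal strings, handled by an exact base-$10^7$ limb
representation internally.

## Synthetic populations

The statistics under test depend only on the hash inputs being *distinct*
strings, so the generators emit InChI-flavoured text that is deliberately
not valid InChI:

* `enumerateStereoisomers()` — for a skeleton with `n` binary stereogenic
  elements, the $2^n$ isomers as a fixed skeleton part plus a sign-pattern
  layer (`"1+,2-,..."`) indexed by the configuration bitmask.  The
  flagship case mirrors a spongistatin-like molecule with 24 tetrahedral
  centers and 2 stereogenic double bonds: $2^{26} = 67{,}108{,}864$
  isomers.  Many such configurations are sterically implausible; that is
  irrelevant to, and ignored by, the hashing statistics.
* `generateSkeletonPopulation()` — counter-injected distinct skeleton
  strings standing in for a constitutional-isomer structure generator
  (the real experiment fed molecular formulae to such a generator;
  tautomer duplication was avoided by formula choice, and is impossible
  here by construction).

Both are deterministic: the stereoisomer stream is ordered by bitmask,
and the skeleton stream embeds its seed and counter in the string body,
so equal configurations give byte-identical streams and different seeds
give disjoint populations.  `hashStereoPopulation()` streams the
enumeration in chunks and retains only the packed truncated hashes
(a numeric vector, ~0.5 GB for the full $2^{26}$ set), never the strings.

What the generators do *not* emulate: real InChI canonicalization, the
empirical length/character distribution of real identifiers, or chemical
validity.  A cryptographic hash is designed to make output statistics
independent of such input structure; passing tests therefore support the
uniform-hash hypothesis for *any* distinct-input population, but they
cannot certify the canonicalization step that produces real identifiers.

## Key forging and the two experiments

`makeKey()`/`forgeKeys()` hash the skeleton part into a 65-bit first
block and the isomer part into a 37-bit second block (SHA-256 via
OpenSSL's libcrypto, batch-looped in C for throughput).

### Second block: direct collision counting

`countCollisions()` reports both the same-hash **pair count**
$X = \sum_v \binom{n_v}{2}$ and the **duplicate count** (inputs minus
distinct values).  The distinction matters in principle — they differ
when three or more inputs share a value — and the pair count is the
quantity $D(k)$ predicts, so it is the primary statistic;
both are reported.

`runSamplingExperiment()` draws `m` uniform size-`k` subsets (without
replacement; repetition `i` reseeds with `(seed + i − 1) mod (2^31−1)`,
making repetitions reproducible and order-independent), counts pairs in
each, and returns the mean, the per-dataset histogram, the running mean
after 1..m repetitions, and $D(k)$.  At $k \ll \sqrt{p}$ the per-dataset
counts are Poisson($D(k)$) to excellent approximation, so the histogram
at $D \approx 0.5$ shows the characteristic ~60/30/7/1 percent split
across 0/1/2/3 collisions rather than a half-and-half pattern.

`runSecondBlockStudy()` defaults to `nStereo = 22` with the classic
k-grid scaled by 1/16 — a population of $2^{22}$ hashed isomers, which
keeps a full `m = 1000` study inside a few minutes on one CPU while
exercising the identical code path as the full $2^{26}$ run (available
by passing `nStereo = 26`).

One statistical subtlety documented here because the tests must live
with it: sampling is from a *finite realized population* whose own pair
count is itself Poisson-distributed around $\binom{N}{2}/p$ (≈ 64 for
$N = 2^{22}$, $p = 2^{37}$).  Conditional on the population, subset
means target $X_{\rm pop} \cdot \frac{k(k-1)}{N(N-1)}$, so at the
largest subset sizes the observed/theory ratio inherits the population's
~12% relative standard deviation on top of the $\sqrt{D/m}$ sampling
error.  A 4-standard-deviation acceptance band around $D(k)$ absorbs
this for typical seeds; the seed used by the reproduction suite is fixed
(42) so the check is deterministic.

### First block: indirect letter statistics

Directly collision-testing a 65-bit space needs ~$10^{11}$ keys
(terabytes); the feasible test is indirect: if short letter windows
appear with exactly the frequencies the layout predicts, the block
behaves as a uniform 65-bit hash.  The probability that a window of
letters occupies a given start position factorizes over the units it
overlaps; each factor is (matching unit strings)/(unit cardinality),
counted by enumeration over the codec table.  For "ABCD" at position 1:

```{r eq3}
sequenceProbabilityAt("ABCD", 1)   # (1/16384) * (676/16384)
```

the first triplet must be exactly "ABC" ($1/16{,}384$) and the second
must be one of the 676 'D'-initial triplets ($676/16{,}384$).  (A
published rendering of this example prints an intermediate factor
"26/512" that is inconsistent with its own final value 2.5183e−6; the
enumeration above reproduces the final value and the published
occurrence table, so the intermediate appears to be a typo.  This
package computes only the layout-consistent form.)  Summing over all 11
start positions and scaling by corpus size gives expected occurrence
counts:

```{r table3}
round(expectedOccurrences("ABCD", 1.2002e9))
round(expectedOccurrences("EDNA", 1.2002e9))
```

`observedOccurrences()` counts per start position (a key can contribute
more than once for one window — the convention that matches linearity of
expectation; at these window lengths the difference from key-level
counting is negligible, but the convention is fixed and shared by both
columns).  `letterPositionFrequencies()` + `inferUnitBoundaries()`
recover the unit structure `[1, 4, 7, 10, 13]` blindly from the zero
pattern of 'E' and 'U'–'Z'.  Normalized views divide by the reference
letter's frequency at position 1 (so 'A' at position 1 reads 1.0000 and
the doublet-start enrichment of 'A' reads
$(26/512)/(676/16384) = 1.2308$), or per letter over the whole block.

`runFirstBlockStudy()` chains generation → forging → scanning in chunks.
Its scan size is a power decision: the rarest of the sixteen classic
4-letter probes has per-key probability $1.6876 \times 10^{-5}$, so at
$n$ keys its expected count is $1.6876\times10^{-5}\,n$ with Poisson
noise.  For the observed/expected ratio of every probe to fall in
[0.9, 1.1] with high probability, ±10% must be several standard
deviations: the reproduction suite uses $n = 6 \times 10^7$ (expected
count ≈ 1013 for the rarest probes, ±10% ≈ 3.2 s.d., joint pass
probability ≈ 0.99 over 16 probes).  At $n = 10^7$ the same band is only
±1.3 s.d. and would fail more often than it passed — a smaller corpus
does not weaken the science, it weakens the test.

## Oracles and validation strategy

The test suite avoids trusting any code path with its own verification:

* collision counting is checked against an $O(n^2)$ all-pairs oracle;
* the probability calculus is checked against *exhaustive enumeration*
  of every valid block of a miniature layout (a 4-letter alphabet,
  range-excluded 48-string triplet and 12-string doublet tables —
  structurally faithful, small enough to enumerate all 27,648 blocks);
* SHA-256 truncation is cross-checked against an independent R binding
  of OpenSSL, and the 256-bit reconstruction against exact hex
  arithmetic;
* encode/decode are property-tested as mutual inverses, including at the
  $2^{65}-1$ endpoint via the decimal-string route.

## Known limitations

* The package emulates the key *format and statistics*, not the key
  *values* of real molecules: no InChI canonicalization, and therefore
  no bit-compatibility with keys computed by the official software.
* Truncation convention (leading bits) and unit bit-order are fixed
  emulation choices; all reported statistics are invariant to them.
* Full-scale campaigns ($2^{26}$ isomers, $10^9$-key scans) are
  supported by the same streaming code paths but are cluster-scale jobs;
  the default configurations are the scaled-down renditions described
  above, and the observed columns of the original full-scale tables
  (which depend on true canonical identifier strings) are reproduced in
  distribution, not value.
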