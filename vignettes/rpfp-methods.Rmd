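---
title: "Recursive prefix-free parsing: model, construction and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive prefix-free parsing: model, construction and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpfp)
```

## The problem

Pangenomes — collections of many similar haplotypes or genome copies —
are highly repetitive, and the indexes used to align reads against them
(run-length encoded BWT, sampled suffix array, sampled LCP array) are
small once built.  The bottleneck is *construction*: a conventional
suffix-array build needs working memory proportional to the total text
length `n`, which for thousands of human haplotypes is far larger than
the final index.

Prefix-free parsing (PFP) attacks this by cutting the text `T` into
overlapping phrases delimited by *trigger strings*: length-`w` windows
whose Karp–Rabin hash is `0 (mod p)`, plus the sentinel window `$^w`
after padding the text to `T' = $^w T $^w`.  Each phrase runs from one
trigger start to the end of the next trigger, so consecutive phrases
overlap in exactly `w` symbols.  The distinct phrases form the
dictionary `D_T` (lexicographically sorted) and the sequence of their
ranks forms the parse `P_T`.  On repetitive text the dictionary stays
small, but `P_T` still has one token per phrase occurrence — on
large collections `P_T` itself becomes the memory bottleneck.

The recursive step parses `P_T` again (window `w2`, modulus `p2`, with
the token 0 playing the sentinel), giving a second dictionary `D_P` of
*meta-phrases* over *meta-characters* (the `D_T` ranks) and a
second-level parse `P_P`.  This package implements the construction of
the RLBWT, sampled SA and sampled LCP of `T$` from `(D_T, D_P, P_P)`
alone: the first-level parse is discarded after the recursion and is
never consulted — the package's bundle object does not even carry it
outside an explicit test mode.

## Why the construction is possible without `P_T`

Three facts carry the whole construction.

**Prefix-free suffixes partition the BWT.**  The set `S_T` of distinct
proper phrase suffixes of length at least `w1` is prefix-free, and every
position of `T$` begins with exactly one element of `S_T` (the suffix of
the phrase occurrence that owns the position).  Hence the BWT rows of
`T$` split into consecutive ranges, one per `alpha` in `S_T` in
lexicographic order, with range length equal to the frequency of
`alpha`.  Frequencies come from phrase occurrence counts, which are
recovered from `P_P`: each meta-phrase occurrence contributes the token
multiplicities of its attributed (non-overlap) offsets.

**Occurrence order descends through the second level.**  Within one
range, occurrences of `alpha` are ordered by what follows them in the
text.  What follows is determined first by the proper *meta-phrase*
suffix `beta` in `S_P` that follows the containing meta-character
(iterating `beta` in lexicographic order — table `T_P` — visits the
occurrences in order), and, for occurrences sharing `beta`, by the
position of the containing meta-phrase occurrence in `BWT(P_P)` — the
grid `G`, an inverted index of `BWT(P_P)` by token.  Two token
comparisons always resolve to character comparisons with a fixed
overlap: differing level-1 phrases that follow a common context share
their leading `w1`-symbol trigger, and differing meta-phrases share
their leading `w2` tokens, so the dictionaries alone settle every tie.

**SA and LCP values come from expansion geometry.**  The `EP` array
stores, per token of `P_P`, the ending position in `T'` of that
meta-phrase occurrence's expansion, computable in one scan because a
token beyond the first `w2` of a meta-phrase advances the expansion by
`|phrase| - w1` symbols.  A descriptor (`alpha`, `beta`, grid position)
resolves through `SA(P_P)` to a token position `k`, and the suffix
position is `EP[k] - |alpha| - (expansion of beta) + 1`, mapped from
`T'` to `T$` coordinates by subtracting `w1`.  The LCP of two adjacent
rows is computed in stages: different `alpha` — character LCP of the two
suffix strings (prefix-freeness guarantees a mismatch); same `alpha`,
different `beta` — token LCP of the betas plus character resolution
inside the first differing phrases; same `alpha` and `beta` — a
range-minimum query over `LCP(P_P)` counts the shared meta-phrases
between the two `BWT(P_P)` rows, then the first differing meta-phrase
pair is resolved token-by-token and character-by-character, subtracting
`w1` per phrase junction and treating the first `w2` tokens of each
meta-phrase as already counted.

The worked three-phrase example is the package's smallest acceptance
check: tokens `(1 2 3)` over phrases `ACCT`, `CTTC`, `TCGG` with
`w1 = 2` expand to 8 characters (12 symbols minus two 2-symbol
junction overlaps):

```{r}
meta_expansion_length(c("ACCT", "CTTC", "TCGG"), c(1, 2, 3), w1 = 2)
```

## Conventions this package fixes

The underlying theory leaves several bookkeeping choices open; the
package fixes them as follows, and the brute-force oracle (an
independent comparison-based suffix sort, sharing no parsing code) is
the arbiter that the combination is coherent.

* **Padding.**  Both ends are padded with `$^w` (`0^w2` at level 2).
  Output coordinates are those of `T$` (length `n + 1`): suffixes
  starting inside the leading padding are excluded from `S_T` (they
  begin with `$` and are not the terminator), the trailing `$^w` suffix
  is kept as the terminator row, and `T'` positions are mapped by
  subtracting `w1`.  Because triggers may fire on windows that straddle
  padding and text, several phrases can start with sentinels; the
  exclusion is therefore by string value (starts with `$`, not equal to
  `$^w`), which exactly matches the leading-padding positions.
* **Suffix length threshold.**  `S_T` and `S_P` contain suffixes of
  length `>= w` with full phrases excluded.  Under this choice every
  position of `T$` has exactly one representative and the sets remain
  prefix-free; the length-exactly-`w` representatives are the trigger
  windows at phrase starts.
* **Record separator.**  Multiple FASTA records are joined with a single
  `'#'`, ordered `'$' < '#' <` all sequence symbols; the padding
  mechanism is `$^w` uniformly, independent of the number of records.
  `N` and other IUPAC codes are ordinary symbols — the index is
  alphabet-agnostic (internally every sequence is a vector of integer
  codes, which is also what makes level 2 the *same* code path).
* **Karp–Rabin hash.**  Polynomial hash with base `2^16` reduced by the
  Mersenne prime `2^31 - 1`, then tested modulo `p`.  With token values
  below `2^21` every intermediate product stays below `2^53`, so the
  hash is exact in double arithmetic and platform-stable.  Worked
  examples fix phrases, not hashes, so the trigger predicate accepts an
  explicit override set of windows (sentinel windows always trigger).
* **Sampling convention.**  SA values are stored at both the first and
  last row of every BWT run (the convention MEM-finding indexes need);
  LCP values at run starts only.  `LCP[1] = 0`.
* **Second-level suffix sorting.**  `P_P` is terminated by the unique
  smallest token 0 and sorted by a generic comparison-based suffix sort
  (radix order over order-preserving key strings); `P_P` is small by
  design, so no specialized suffix-array algorithm is warranted.  The
  LCP of `P_P` is computed Kasai-style and served through a sparse-table
  RMQ (`O(m log m)` space, `O(1)` queries).
* **Intervals.**  Half-open 0-based ranges internally (`T_T` rows
  partition `[0, n + 1)`); 1-based closed rows and positions in every
  user-facing table.
* **On-disk formats.**  Versioned plain-text formats (header line plus
  one record per line) for dictionaries, parses and the three index
  files.  A dictionary line is the phrase's integer token codes; this
  representation is identical for character-level and token-level
  dictionaries, which keeps one reader/writer for both levels.

## Tunable parameters

* `w1`, `p1` (defaults 10, 100): level-1 window length and hash modulus.
  The expected phrase length is about `p1 + w1` symbols; larger `p1`
  means fewer, longer phrases (smaller `P_T`, larger dictionary
  entries).  Defaults follow common practice for genome-scale texts.
* `w2`, `p2` (defaults 5, 11): the level-2 analogues, deliberately
  smaller because `P_T` is already orders of magnitude shorter than the
  text.  No published guidance exists for these; the defaults are the
  package's own choice and both are fully configurable.
* Test suites use small values (`w in {2,3,4}`, `p in {3,5,11}`) to
  densify triggers on short synthetic texts — with the default
  parameters a 200-symbol text would parse into a single phrase and
  exercise nothing.

## What the synthetic generator emulates — and what it does not

`generate_pangenome()` produces a uniform random base genome and
haplotypes derived by i.i.d. per-site substitutions and geometric-free
(uniform length `1..max_indel`) insertions/deletions;
`generate_copies()` produces the identical-copies regime of near-clonal
collections.  These reproduce the *repetition structure* the
construction exploits (long shared phrases, dictionaries that saturate
as copies accumulate) and are fully deterministic given a seed
(Mersenne-Twister, fixed algorithm, never the clock).

They do not emulate realistic variant spectra, mutation hotspots,
structural variation, diploid phasing or chromosome-scale length — so
passing tests demonstrate correctness of the construction on texts with
pangenome-like repetitiveness, not calibrated performance on real
cohorts.  Correctness is, however, alphabet- and structure-agnostic
(the oracle-equality suite mixes DNA and binary alphabets precisely to
avoid over-fitting conventions to ACGT).

## Verification strategy and problem sizes

Every module is tested against an independent oracle: exhaustive window
scans for triggers, literal expansion for parses, direct position scans
for `EP`, fixed-width decimal re-encoding for the parse suffix sort,
linear scans for the RMQ, and — end to end — the brute-force
`naive_index()`, which sorts the suffixes of `T$` by direct comparison
and never touches parsing code.  The randomized equivalence suite runs
200 cases with `n` between 50 and 2000 over the parameter grid above
and requires byte-identical BWT, run decomposition, SA samples at run
boundaries and LCP samples at run starts; the repetition-scaling check
builds 64 identical copies of a 1 kb genome and asserts that the
level-1 dictionary grows by at most two phrases over the 2-copy
dictionary while `|D_P| + |P_P| < |P_T|`.  These sizes keep the full
suite around two minutes on one CPU while still covering sparse- and
dense-trigger regimes, both alphabets, repetitive and random texts, and
the degenerate single-phrase cases.

## Known limitations

* The construction is in-memory and single-threaded; `n` in the tens of
  millions is practical, external-memory scale is not the goal.
* The brute-force oracle is quadratic-ish and guarded at
  `n + 1 <= 10^5`.
* Recursion depth is fixed at two (parse of the parse); deeper recursion
  would need the level-2 machinery generalized to level `k`.
* The index is construction-only: LF-stepping, locate and MEM-finding
  queries over the produced RLBWT/SSA/SLCP are downstream concerns.
* Token values (dictionary ranks) are capped at `2^21 - 1` by the exact
  double-precision hash; texts whose level-1 dictionary exceeds two
  million phrases need a wider hash.
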