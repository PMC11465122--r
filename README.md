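# rpfp — recursive prefix-free parsing for pangenome index construction

`rpfp` builds the three arrays at the heart of run-length compressed
full-text indexes — the run-length encoded Burrows–Wheeler transform
(RLBWT), the suffix array sampled at run boundaries, and the LCP array
sampled at run starts — for a collection of similar sequences (a
pangenome), using **recursive prefix-free parsing**.  It is aimed at
people building or studying compressed indexes for repetitive
collections: many haplotypes of the same chromosome, thousands of
near-identical viral isolates, or any text whose size vastly exceeds
its information content.

## The method in brief

Prefix-free parsing (PFP) pads the text to `T' = $^w T $^w` and cuts it
at *trigger strings* — length-`w` windows whose Karp–Rabin hash is
`0 (mod p)` — into overlapping phrases (consecutive phrases share
exactly `w` symbols).  The distinct phrases form a lexicographically
sorted dictionary `D_T`; the sequence of phrase ranks forms the parse
`P_T`.  On repetitive text `D_T` stays small, but `P_T` grows with the
number of phrase occurrences and becomes the construction-memory
bottleneck on large collections.

`rpfp` therefore parses the parse: running PFP on `P_T` (window `w2`,
modulus `p2`) yields meta-phrases `D_P` over the `D_T` ranks and a
second-level parse `P_P`, after which `P_T` is **discarded**.  The
BWT, sampled SA and sampled LCP of `T$` are then constructed from
`(D_T, D_P, P_P)` alone:

* the proper phrase suffixes of `D_T` (a prefix-free set) partition the
  BWT rows into consecutive ranges, with frequencies recovered from
  `P_P`;
* within a range, occurrences are ordered by the proper meta-phrase
  suffix that follows them (table `T_P`, lexicographic order) with ties
  broken by the grid `G`, an inverted index of `BWT(P_P)`;
* SA values come from the `EP` array of meta-phrase ending positions
  (`SA = EP[k] - |alpha| - |expansion of beta| + 1`, shifted to `T$`
  coordinates);
* LCP values at run starts come from a staged comparison — suffix
  strings, then meta-phrase tokens via a range-minimum query over
  `LCP(P_P)`, then characters — subtracting `w1` per phrase junction.

A brute-force oracle (`naive_index()`, an independent comparison-based
suffix sort) provides ground truth on small texts, and a synthetic
pangenome generator provides test collections with the repetition
structure the method exploits.

## Worked example

```r
library(rpfp)

set <- generate_pangenome(pangenome_spec(base_length = 300, n_haplotypes = 4,
                                         sub_rate = 0.02, indel_rate = 0.005,
                                         seed = 42))
txt <- assemble_text(set)
txt
#> rpfp_text: n = 1190, alphabet = {$, #, A, C, G, T}

b <- build_rpfp(txt, trigger_config(4, 5), trigger_config(2, 3))
b
#> rpfp_bundle: n = 1190, w1 = 4, p1 = 5, w2 = 2, p2 = 3
#>   |D_T| = 104 phrases (1000 tokens), |D_P| = 63 meta-phrases (334 tokens), |P_P| = 88

idx <- rpfp_index(b)
idx
#> rpfp_index: n = 1190, r = 354 runs (n/r = 3.36), w1 = 4, p1 = 5, w2 = 2, p2 = 3
head(idx$ssa, 3)
#>   run start_row sa_first sa_last
#> 1   1         1     1191     901
#> 2   2         5        1       1
#> 3   3         6      598     302

compare_index(rpfp_index(b, full_arrays = TRUE), naive_index(txt))
#> rpfp_diff: no differences
```

Four haplotypes (1190 symbols with `#` separators) parse into 104
distinct phrases whose 260-token parse re-parses into 88 second-level
tokens; the 1191-row BWT collapses to 354 runs.  `idx$ssa` holds the
suffix-array samples at the first and last row of each run (the first
run starts with the terminator row, SA value `n + 1 = 1191`), `idx$slcp`
the LCP at each run start, and `compare_index()` confirms the
construction equals the brute-force oracle row for row.

A command-line wrapper with `synth`, `parse`, `build` and `check`
subcommands is installed at `system.file("cli", "rpfp.R", package =
"rpfp")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","rpfp.R",package="rpfp"))')" \
  build -i pangenome.fa -o idx --w1 10 --p1 100 --w2 5 --p2 11
```

## Scope

Construction only: LF-stepping, locate and MEM-finding queries over the
produced index, thresholds, VCF-direct parsing, multithreading and
external-memory engineering are out of scope.  See
`vignettes/rpfp-methods.Rmd` for the model, the conventions the package
fixes (padding, suffix-length threshold, hash, sampling) and known
limitations.
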