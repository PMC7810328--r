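---
title: "Code-set design and correlation-based sequence matching with gacodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Code-set design and correlation-based sequence matching with gacodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cross-correlation is an attractive primitive for sequence comparison
because a coherent optical correlator (the classic Vander Lugt 4f
arrangement) evaluates the full 2D correlation surface of two images in a
single pass of light: encode a reference sequence as a binary raster on one
spatial light modulator, a query on another, and every alignment offset is
scored simultaneously. Whether the output is *usable*, however, depends
almost entirely on how symbols are encoded. If the small binary matrices
("codes") chosen for A, C, G and T overlap each other appreciably at
shifted offsets, the surface fills with junk peaks (overlap noise) that
drown the informative full peaks.

`gacodes` addresses the encoding side of that system. It provides:

1. a cost function that measures the overlap noise of a candidate code set
   exhaustively over its minimal tiling neighbourhoods,
2. a genetic algorithm (GAC) that searches for *zero-score* code sets —
   sets whose worst off-match correlation stays below a chosen acceptance
   margin,
3. an FFT correlator (ideal, and pupil-band-limited to emulate the optical
   diffraction limit) with query detection and k-mer counting on encoded
   rasters, and
4. a synthetic benchmark harness and a throughput model for the
   display-bound optical setup.

## Code sets and the overlap-noise cost

A code set assigns each of `K` symbols a binary `d x d` matrix with exactly
`N` ones (1D sets use `1 x d` rows). Uniform weight `N` is the load-bearing
choice: a query of `L` matching symbols always produces a full peak of
exactly `L * N`, so detection thresholds can be derived instead of tuned
per query.

Overlap noise is evaluated on *c-grids*: 2 x 2 tilings of codes (1 x 2 in
1D). Tilings of any larger extent decompose into 2 x 2 blocks by linearity
of correlation, so checking all `K^4` grids with all `K` sliding codes —
`K^5` states, 1024 for DNA with `d = 3` — bounds the noise of arbitrarily
long encoded sequences. `overlap_cost()` counts every (state, offset) whose
correlation value reaches `N - E`, where `E` is the acceptance margin, and
*excludes* exact alignments of a code over its own symbol (those are the
informative peaks). Exact alignment over a *different* symbol counts, which
is what penalises duplicate or near-duplicate codes.

Two conventions deserve a note because the boundary case matters:

* **The invalid rule is `>= N - E`, not `> N - E`.** With a strict rule an
  `E = 0` set could never score at all (no overlap exceeds `N`), yet random
  `d = 3, N = 2, E = 0` sets plainly are noisy (our stored random fixture
  scores 928). The non-strict rule makes `E = 0` mean "junk must stay below
  the full-peak height", which is the usable reading.
* **Cost granularity is per (state, offset) pair**, not per state: it gives
  the genetic algorithm a gradient between "one bad offset" and "many bad
  offsets" instead of a flat plateau.

`relative_threshold()` returns `E / N`, which makes margins comparable
across set shapes (`E = 11, N = 32` gives 0.34; all `E = 0` sets give 0).

## The genetic algorithm

An individual is the flat vector of `K * N` cell indices (chunk `k` holds
symbol `k`'s one-positions). Mutation resamples one entry of one chunk into
a free cell, so chunk uniqueness is invariant; crossover cuts only at chunk
boundaries, so offspring inherit whole codes. Each cycle selects the two
fittest members, recombines, mutates each offspring with probability 0.3,
and accepts the pair — replacing the two worst members — only when both
beat the current worst fitness. Fitness is minus the overlap cost;
evolution stops at zero or at the cycle budget.

The population size (50), mutation probability (0.3) and budget (200 000
cycles) are engineering defaults: the selection scheme is elitist enough
that the best fitness is non-decreasing, and the repeated-mutation
initialisation keeps early diversity adequate for the small `d = 3` search
spaces. Convergence is stochastic — some seeds stall in local optima at
cost 32–128 — so the intended use is to try a handful of seeds; roughly
half converge within 20 000 cycles for the `d = 3` DNA shapes.

Among zero-score sets of one shape we prefer the one with the smallest
cross-talk constant `C` (below): zero score bounds the *worst* junk value,
while `C` is the *mean* aligned cross-talk, and every detection margin in
the matcher improves as `C` falls. The fixtures under `inst/extdata/` were
produced this way by `gac_evolve()` itself.

## Encoding and the correlator

`encode_sequence()` lays codes left-to-right, 42 columns per row by default,
wrapping rows downward; each code may carry a free boundary of `pad` zero
pixels on all four sides (halo suppression in the band-limited mode; the
two- versus ten-pixel comparison is the standard experiment). A code is
centred in its `(d + 2 pad)^2` cell, giving a symmetric halo. Queries that
span a row wrap are *not* specially handled: the break is a known,
quantified failure mode (the cutoff error), deferred exactly as in the
underlying system design.

`xcorr2()` computes the full linear correlation by zero-padded FFTs
(padded to 2-3-5-smooth sizes; never circular, which would fabricate
wrap-around peaks the optical system cannot produce). In ideal mode with
binary inputs the surface is rounded to integers before thresholding —
float FFT dust is the only "system noise" the behavioural simulator has.
Optical mode multiplies each forward spectrum with a hard-edged circular
low-pass mask at the coherent cutoff `f0 = D_xp / (2 lambda z_xp)`;
apodization and aberrations are deliberately not modelled. The sampling
bounds `du <= lambda z_xp / (2 D_xp)` and `L <= S du` are exposed with a
default 5% derating. The exit-pupil distance has no authoritative default
and must be supplied.

## The peak model

For a contained, row-aligned query of length `L` at substitution rate `M`,
the true-alignment peak is

```
peak = L * N * (1 - M) + L * C * M
```

where `C` is the mean aligned overlap between a symbol's code and the code
of a uniformly chosen *different* symbol. `C` is a property of the bit
patterns, so `calibrate_C()` estimates it per set by Monte-Carlo (fully
substituted random sequences, read at the exact alignment); for our stored
`3 x 3 / N = 3` set the exact value is 1.167 and the calibration recovers
it to two digits. Normalized by `L`, the model gives per-symbol
coefficients (3.00, 2.82, ... 1.92 for `N = 3, C = 1.2` at rates 0–60%)
that the benchmark's empirical peak means track within a few parts per
thousand.

## Detection thresholds

`detect_query()` uses the model threshold
`L * (N (1 - M_max) + C * M_max) - slack`, with `slack = E L / 2` by
default (half the margin the set guarantees). The benchmark adds a second,
exact guard: under the null of an absent query, a lattice offset's value is
a sum of `L` draws of the aligned-overlap distribution over uniform ordered
symbol pairs, whose mean `mu` and variance `sigma^2` are computed exactly
from the code set (`alignment_null()`). The effective threshold is

```
max( model threshold at M_max,  L mu + z sqrt(L sigma^2) ),   z = 5
```

The guard matters for short queries: with `N = 3, C ~ 1.2`, the null mean
is `mu ~ 1.63` per symbol while the model threshold at `M_max = 0.65` is
`1.86` per symbol — a gap that `sqrt(L)`-scale fluctuations cross easily at
`L ~ 50`. The consequence, visible in the benchmark output, is the expected
one: errors concentrate in short, heavily mutated queries, sensitivity is
perfect through 40% substitution and degrades gracefully at 50–60%.

## The synthetic benchmark

`random_genome()` draws uniform i.i.d. symbols. That emulates the
composition of the evaluation protocol (random subsequences of a bacterial
genome, mutated at 0–60% in 10% steps) but not repeats, skew or low
complexity regions of real genomes — so a perfect score here shows the
*coding and detection machinery* works, not that real-genome specificity
would be identical. Scene size is 10 000 symbols (100 x 100 codes),
queries default to 30 per sweep with lengths 50–1500, a scale that keeps
the full sweep under a minute while preserving every structural feature of
the full protocol (481 scenes of a 4.8 Mbp genome; 303 queries to 4500 bp;
2121 mutated queries).

Two deliberate benchmark design choices:

* **Query starts are drawn on the raster row grid** (`align_rows = TRUE`).
  A 2D-wrapped query matches its scene's raster only when its row phase
  agrees; random-phase starts would measure the deferred row-break problem
  everywhere instead of at the quantified cutoff-error site. Scene
  boundary-straddling queries are annotated and excluded from the tallies.
* **Mutations are coupled across rates** (nested positions, shared
  replacements). Marginally each copy still has exactly
  `round(rate * length)` uniform substitutions, but each query's peak is
  then exactly non-increasing in rate, so a 30-query sweep shows the true
  monotone sensitivity trend rather than sampling noise.

`quadruple_metrics()` reports Se, Sp, Ex and Er from the per-(query, scene)
confusion counts; undefined ratios are `NA`, never 0.

## k-mer counting and the cutoff error

`count_kmers()` encodes the k-mer as one code row and counts *all* surface
offsets reaching `k N - slack`. For a zero-score set no junk offset can
reach the threshold (each symbol contributes at most `N - E - 1` off
alignment), so the count equals the exact overlapping count minus
occurrences broken across row wraps — e.g. the 18-symbol reference wrapped
at 6 codes per row where one of two `AATC` occurrences spans the wrap: 1
found of 2 real, relative error 0.5. Noisy sets additionally over-count
through junk peaks; on a 1260 bp sequence with all 1–4-mers the stored
zero-score set averages ~7% relative error (all of it cutoff) against ~11%
for the random score-928 set. Restricting the count to lattice offsets
(`lattice = TRUE`) is available for diagnostics but hides precisely the
junk peaks the zero-score design suppresses, so it is not the default.

## Throughput model

For a 4K scene (4096 x 2160 pixels) and `3 x 3` codes,
`nucleotides_per_scene()` counts whole codes per dimension —
`floor(4096/3) * floor(2160/3) = 1365 * 720 = 982800` — since a code
cannot straddle the scene edge. `scene_count()` (a ceiling: a partially
filled frame still costs a frame) then prices a 3.1 Gbp reference at 3154
scenes, two million 500 bp queries at 1018 (exactly 1017.5 frames of
payload) and 870 000 4000 bp queries at 3541; at a 2.44 MHz
holographic-disc switching rate `search_time()` predicts 1.32 s and 4.58 s
respectively. These are display-bound model predictions (scene pairs per
switching rate), not measurements.

## Numerical and degenerate-input choices

* Correlation offsets are 1-based in surfaces; alignment of a query at
  reference position `(r, c)` peaks at `(r + Hq - 1, c + Wq - 1)`.
* Rasters of sequences shorter than one row are trimmed to the occupied
  width, so sliding ranges stay meaningful for short queries.
* `mutate_sequence()` uses base R `round()` (ties to even) for the
  substitution count; rate 0 returns the input unchanged.
* Selection ties in the GA break toward the lower member index; runs are
  bit-reproducible given a seed.
* `E >= N`, duplicate cells in a chunk, out-of-alphabet symbols, empty
  sequences and shape mismatches raise validation errors; GA
  non-convergence is reported in the result (and by exit status 1 from the
  CLI), never raised.

## Known limitations

* Substitutions only: indels shift the alignment lattice and are out of
  scope (as in the underlying evaluation protocol).
* Row-break (cutoff) misses are quantified, not fixed; a wrap-aware
  encoding is future work.
* The optical mode models only the coherent cutoff; SLM quantisation,
  aberrations, partial coherence and detector noise are not simulated.
* The GA is not guaranteed to converge for a given seed; large shapes
  (`d = 9, N = 32`) are supported by the cost machinery but evolving them
  is compute-heavy.
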