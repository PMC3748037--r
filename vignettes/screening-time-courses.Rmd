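---
title: "Screening omics time courses by dynamic time warping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening omics time courses by dynamic time warping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Stressor-induced biological responses unfold with different kinetics in
different measurables: a gene may follow the same trajectory as a phenotypic
marker, only delayed by hours. Pearson correlation across time points, which
compares values measured *simultaneously*, misses such associations.
Dynamic time warping (DTW) aligns two time courses by allowing local
stretches and delays of the time axis and measures how well they match
*after* the optimal alignment, so delayed but kindred trajectories score
well. `warpscreen` turns this idea into a screen: thousands of measured
entities (genes, metabolites, proteins) against a handful of reference
endpoints, or the same entities measured under two conditions, with
permutation-based significance and FDR control.

## The alignment model

Both series are first scaled per series (`scale_series()`; the default
`unit_variance` autoscaling subtracts the mean and divides by the sample
(n−1) standard deviation, so a gene on a log2 scale and a cell-cycle
fraction in percent become comparable). For scaled series
$a_1..a_n$, $b_1..b_m$ and a local distance $d(i,j) = |a_i - b_j|$
(or its square), the accumulated cost is

$$D(i,j) = d(i,j) + \min\{D(i-1,j),\ D(i,j-1),\ D(i-1,j-1)\}, \qquad
D(1,1) = d(1,1),$$

minimised over all monotone paths from $(1,1)$ to $(n,m)$ with unit steps.
Under this default `fewer_delays` pattern every visited cell pays its local
cost once, so a path that introduces extra delays is longer and pays for
them — the built-in bias towards alignments with fewer delays. The
alternative `symmetric_weighted` pattern counts the local cost of a
diagonal step twice (the classic weighted symmetric recursion), removing
the preference for diagonal moves; which of the two a given historical
analysis used is rarely documented, so both are exposed and recorded in the
run summary. There is no window constraint and no open-ended alignment:
the series involved are short (9–20 points) and the screen is about
whole-course similarity. Traceback ties are broken deterministically
(diagonal, then the $(i-1,j)$ predecessor, then $(i,j-1)$), so the reported
path is reproducible; the distance is unaffected by ties.

Time-point values label the plot axes only. Warping operates on index
order: with no principled local cost for unequal spacing on these short
grids, unequal spacing does not change the alignment.

## Significance

A DTW distance alone says nothing about chance. The null model treats the
temporal order of each series as uninformative: each permutation draw
shuffles the order of the entity's values and, independently, the order of
the endpoint's values, and re-runs the alignment. With $B$ draws the
p-value is the add-one estimator

$$p = \frac{1 + \#\{d_{\mathrm{null}} \le d_{\mathrm{obs}}\}}{B + 1},$$

which is never exactly zero (a zero would poison the FDR step) and counts
ties conservatively. Null distances that are mathematically tied with the
observed one can differ in the last floating-point bit because the same
path costs are summed in a different order; ties are therefore counted
with a $10^{-9}$ relative tolerance. $B$ defaults to 1000; 199 is used in
the fast checks below, which resolves p down to 0.005 — enough for a 5%
FDR screen of hundreds of entities.

Benjamini–Hochberg correction (`bh_adjust()`, the standard step-up) is
applied per family: across all entities for one endpoint in the endpoint
screen, and across the label intersection in the matched screen. Families
are *not* pooled across endpoints, since each endpoint asks its own
question and results are reported per endpoint. The default significance
threshold is q ≤ 0.05.

**A caveat that the benchmark quantifies.** Real biological series are
smooth, and smooth series look less like their own order-permutations than
white noise does, so permutation p-values for smooth series overstate
significance. The decoy arm of the benchmark (independent smooth pairs)
shows exactly this: decoys are flagged far above the nominal rate, while
white-noise decoys are not. The ranking is still useful; for long, smooth
series a stricter threshold such as q ≤ 0.01 is advisable, which is why
the threshold is a parameter rather than a constant.

## Reproducible permutation streams

One run seed drives everything. Each entity's permutation stream is seeded
by mixing the run seed with a 31-bit hash of the entity label (plus the
endpoint label in the endpoint screen), so results are independent of row
order and of which subset of entities is screened together. In the matched
screen the two series of a pair additionally enter the draw in a canonical
order (lexicographic on scaled values) before the two permutation streams
are assigned; DTW distance is symmetric, so swapping the two input
matrices then changes neither distances nor p-values — swap invariance is
exact, not approximate. All derived seeds stay below $2^{31}$.

## The time-course pre-filter

`filter_time_courses()` first removes rows with missing values, then keeps
a row only if at least one time point deviates from the row mean by at
least `z_threshold` (default 2) row standard deviations. Mean and sd are
taken **across the row's time points**: the input matrix is assumed
already replicate-averaged, so within-gene-across-time is the only spread
available. This is an interpretive choice — a replicate-level variance
filter is a different (out of scope) instrument. The criterion is a
z-score, hence scale-equivariant; constant rows are always dropped (the
raw inequality would vacuously retain them, and they cannot be
unit-variance scaled). Linear ramps fail the default threshold on 9
points; spikes pass — the filter selects series with a pronounced
excursion, not merely a trend.

## The synthetic benchmark

The generator (`make_benchmark()`) emulates a matched two-condition
experiment with known ground truth:

* **Smooth mother series.** `smooth_series(L)` draws
  `max(4, ceiling(L/5))` standard-normal knots at evenly spaced positions
  spanning `[1, L]` and evaluates a cubic spline at the integer grid.
  Smoothness is the point: it recreates the anti-conservative regime of
  real data.
* **Shift by windowing.** Each matched pair takes two length-20 windows of
  a length-29 mother, offset by the cell's shift (0–9 points), so shifted
  copies share no wrap-around artefacts and the true alignment is the
  front-loaded shift path returned by `intended_path()`.
* **Noise ladder.** Independent Gaussian noise with sd equal to
  `0.1 × level × sd(mother)`, levels 1–10, i.e. 10%–100% of signal sd.
  Whether the original ladder started at exactly zero is unknowable;
  level 1 is nonzero here, and an explicit `noise_multipliers` ladder
  (including 0) can be supplied for zero-corruption checks.
* **Decoys.** Unmatched pairs of independent smooth series sharing a
  label, to measure the false-match rate on smooth data.

The default configuration is 10,000 matched rows (100 balanced
shift × noise cells) plus 1,000 decoys, length 20. The routine checks in
this package run the same design at 400 + 40 rows (4 per cell) with
B = 199, which finishes in seconds; grid cells are then coarse (steps of
25%) but every trend assertion is on whole rows or columns of the grid.

`evaluate_benchmark()` scores a matched screen against the truth table:
per-cell detection (flagged at the chosen FDR) and exact shift-pattern
recovery, where "exact" is literal pair-sequence equality with the
intended path — co-optimal alternatives count as misses.

What the generator does **not** emulate: replicate structure and
replicate-level variance, platform-specific noise (heteroscedastic,
count-based, or autocorrelated), missing values, and correlated entities
(every pair is independent). Passing benchmarks therefore demonstrate the
screen's statistical machinery under a clean, favourable signal model, not
performance on any particular platform's data.

### What the benchmark shows

Two regularities emerge at either scale, and they mirror each other:

* Detection degrades with shift but survives noise at small shifts: the
  zero-shift column stays high even at the top of the noise ladder.
* Exact shift-pattern recovery is far more fragile than detection. Even at
  10% noise, a warp slightly different from the intended one is often
  genuinely cheaper, and on noiseless shifted pairs the optimal path
  equals the front-loaded intended path essentially always at shifts ≤ 2
  but only ~50–80% of the time at large shifts — an equally long path that
  spends its delays mid-course, where the series is flat, can cost less.
  The practical reading: trust the entity lists more than the recovered
  shift patterns, and prefer sampling designs whose expected delays span
  at most a couple of grid units.

## Numerical and interface choices

* Sample (n−1) sd everywhere (scaling, filter, noise ladder).
* Degenerate inputs fail loudly and early: series shorter than 2 points,
  zero-variance series under unit-variance scaling (screens drop such
  entities with a warning and list them in the run summary), duplicate row
  labels, empty label intersections, shape mismatches.
* Reports per screen: `significant_entities.txt` (sorted by q, then p,
  then label), `run_summary.txt` (every parameter needed to replay the run
  plus the best entity regardless of threshold), a before/after warp
  figure per significant entity, an observed-vs-permuted distance
  histogram, and the best entity's null histogram with the observed
  distance marked. JPEG by default, PNG optionally; images are for
  inspection and carry no numeric contract.
* Matrices travel as TSV with row labels and a header, written at 17
  significant digits so a write/read round trip is bit-identical.
* The command-line interface (`inst/cli/warpscreen.R`) is a thin layer
  over the exported functions with subcommands `filter`, `endpoint`,
  `matched`, `simulate`, `evaluate`, optional YAML config, and parameter
  logging to stderr.

## Known limitations

* Permutation p-values are anti-conservative for smooth series (by
  design of the null, not a bug); use stricter q thresholds there.
* Exact-path percentages depend on the strict equality convention and on
  the noise scale of the generator; comparing them across studies with
  different noise conventions is not meaningful.
* No window constraints, derivative DTW, open-ended alignment,
  multi-dimensional DTW, block permutations, or pathway
  over-representation — deliberate non-goals.
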