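---
title: "Assessing ranking stability in benchmark challenges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing ranking stability in benchmark challenges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benchrank)
```

## The problem

Benchmark competitions rank $p$ competing algorithms by a performance metric
evaluated on $n_k$ test cases in each of $m$ tasks. The published ranking is a
point estimate: it depends on which test cases happened to be in the test set
and on the ranking scheme the organizers chose, yet most challenge reports
convey neither source of uncertainty. benchrank treats the ranking itself as
the statistic of interest and quantifies its sampling variability (by
bootstrapping test cases), its robustness to the ranking scheme (by comparing
schemes), and its generalizability across tasks (by consensus rankings and
task-similarity analyses).

The input is deliberately minimal: a long-format table with one row per
(task, algorithm, test case) carrying the metric value, plus a single
direction flag (`smallBetter`) for the whole analysis. Metrics like the Dice
similarity coefficient, which dominates segmentation benchmarks, are
larger-is-better on $[0, 1]$; error metrics such as the Hausdorff distance
would use `smallBetter = TRUE`.

## Ranking schemes and the tie convention

Three schemes are implemented, all ending in ranks that obey the challenge
min-rank convention — tied algorithms share the smallest rank they span, so
two tied winners are both rank 1 and the next algorithm is rank 3:

* **aggregate-then-rank** (`aggregateThenRank`): aggregate each algorithm's
  metric values across cases (mean, median with the mid-point convention, or
  an empirical quantile with linear interpolation — quantile type 7), then
  rank the aggregates.
* **rank-then-aggregate** (`rankThenAggregate`): rank algorithms within each
  case, aggregate the per-case ranks per algorithm, re-rank the aggregates.
* **test-based** (`testThenRank`): for every ordered pair (A, B) a one-sided
  paired Wilcoxon signed-rank test of "A superior to B" is computed, Holm's
  step-down adjustment is applied over all $p(p-1)$ one-sided hypotheses
  within the task, and each algorithm is scored by how many competitors it
  significantly outperforms; equal scores share a rank. The family for the
  Holm adjustment is a genuinely open design point — we adjust over all
  ordered pairs within one task, the most conservative reading compatible
  with the significance map, and keep it per task in multi-task analyses.

The signed-rank test drops zero differences before ranking the magnitudes
(the classic convention; metric ties do occur with bounded scores) and logs
the dropped count. The exact null distribution of the positive-rank sum is
used for up to 25 nonzero pairs. It is computed by a subset-sum convolution
over the (possibly tied, hence averaged) ranks, which is equal to full
enumeration of all $2^n$ sign assignments but costs $O(n \cdot \sum r_i)$;
above 25 pairs a normal approximation with continuity correction and
tie-corrected variance takes over. The threshold is configurable
(`exactLimit`).

## Missing values

An algorithm that fails to produce a value for a case must not be rewarded
for the omission: each absent or `NA` cell of a task's cases × algorithms
grid is set to an unfavorable value before any analysis. The default is 0 for
larger-is-better metrics (the natural floor for non-negative scores) and the
observed per-task maximum for smaller-is-better metrics; both are
overridable. Two deliberate choices: imputation only applies to algorithms
that participate in a task at all — an algorithm with no record in a task is
excluded from that task's ranking and flagged, rather than having an entire
task's performance fabricated — and imputed values participate in rankings
*and* significance tests, which the validation report states explicitly.

## Bootstrap stability

`bootstrapRankings` draws $b$ bootstrap samples of a task ($n$ cases drawn
with replacement from its $n$ cases; a case drawn twice counts twice in
aggregates and tests), re-runs the complete ranking procedure on each sample
— for test-based ranking this includes re-running every test and the Holm
adjustment per replicate, so each replicate ranking is internally consistent
— and summarizes:

* the rank-frequency matrix (blob plots: blob area ∝ relative frequency of a
  rank),
* per-algorithm median ranks and percentile intervals (default 95%, i.e. the
  2.5th–97.5th percentiles, linear interpolation between order statistics),
* Kendall's $\tau$ between each replicate ranking and the full-data ranking
  (violin plots). $\tau$ is bounded in $[-1, 1]$, making distributions
  comparable across tasks.

$b = 1000$ is the conventional default. Replicates whose ranking collapses to
all-ties are kept (never dropped); their $\tau$ to the full ranking is
undefined and stored as `NA`, excluded from violins, and counted in the
report. Tasks with fewer than 20 cases carry a caution flag: with so few
cases the bootstrap distribution can be a poor estimate of the true sampling
distribution.

We use the tie-corrected $\tau_b$, computed from explicit concordance /
discordance counts rather than a normalized-covariance formula so that
identical and inverted orderings yield exactly $\pm 1$ in floating point.
When either ranking is completely tied $\tau_b$ is undefined and signaled as
`NA` with a warning. Spearman's footrule (sum of absolute rank differences)
and Spearman's distance (sum of squared differences) are the companion
distance measures; with tied ranks they difference whatever rank convention
the caller supplies.

## Consensus across tasks

For multi-task challenges, `consensusRank` aggregates per-task rankings with
each task weighted equally, independent of its sample size or stability. The
default mean-rank method first converts each task's ranks to the average-rank
tie convention (ties replaced by the mean of the spanned ranks — required for
the equivalence below), averages them per algorithm, and min-tie ranks the
averages. This is exactly the distance-minimizing consensus under Spearman's
distance, and the package tests verify the equivalence by brute-force
enumeration over all orderings. The explicit distance-minimizing variant
enumerates all $p!$ orderings for $p \le 8$ and falls back to mean-rank
initialization plus pairwise-swap descent beyond; when several orderings tie,
the lexicographically smallest rank vector is reported (the non-uniqueness
has no canonical resolution, so we pick a deterministic one).

Task similarity uses the same distances: `dendrogramData` clusters tasks
hierarchically (complete linkage by default) on the footrule distance between
their rankings, and `networkData` builds the complete task graph with target
edge lengths $\exp(0.05 \, d)$ — exponential in the distance with growth rate
0.05 to accentuate large distances — and colors each node by its unique
winner, leaving tasks with tied winners uncolored.

## Figures

Every figure has a pure computation step (testable without graphics) and a
rendering step (`renderFigure`): dot-and-box plots with seeded horizontal
jitter; podium plots (per-case placements connected by "spaghetti" lines,
with the place-frequency bars underneath; ties broken randomly under a
logged seed so each case's placement is a permutation; refused above 30
algorithms in favor of a top list); ranking heatmaps (per-case min-tie rank
counts; columns sum to $n$); line plots across ranking schemes (parallel
lines = robust ranking); blob plots (bootstrap, across-task, and stratified
variants all reuse `blobData` with a different grouping); violin plots of the
$\tau$ distribution (the violin input *is* the `tauToFull` output, nothing is
recomputed); significance maps (yellow = significantly superior, blue = not);
dendrograms and network graphs. Axis order always follows the selected
ranking (single task) or the consensus (multi task). Blob areas scale
linearly with frequency (`scale_size_area`, capped at 8 mm) and violins use
the default density bandwidth; neither choice affects any computed number.

## Synthetic study conditions

Two generators span the extremes of challenge behavior and make every
analysis testable without real data:

* `generateIdeal(n = 50)`: five algorithms draw uniformly from the disjoint
  strata $[0.9, 1), [0.8, 0.9), \dots, [0.5, 0.6)$ — a Dice-like score with
  a clear, indisputable ranking. For *any* draw all schemes return ranks
  1..5, every bootstrap replicate reproduces the full ranking, all
  $\tau = 1$, and the significance map is fully significant above the
  diagonal.
* `generateRandom()`: 250 draws from Normal(mean 1.5, variance 1) are pushed
  through the logistic function $1/(1+e^{-x})$ onto $(0,1)$ (a skewed,
  bounded distribution) and assigned to the five algorithms in draw order —
  50 cases with no systematic difference whatsoever, so any significance is a
  false positive and the only correct ranking is one shared rank.

`generateCustom` mixes such tasks with configurable $n$, $p$ and a
missingness rate for multi-task fixtures; "ideal" tasks with $p$ algorithms
use strata of width $1/(p+4)$ so the separation structure scales with $p$.

What the generators do *not* emulate: heteroscedastic per-case difficulty,
correlated algorithm errors on hard cases, heavy outliers, or drop-out
patterns of real submissions. Tests passing on these conditions demonstrate
correctness of the machinery and its behavior at the stability extremes, not
performance claims about any real challenge.

## Reproducibility and problem sizes

All randomness (bootstrap resampling, podium tie-breaks, jitter, network
layout) is seed-controlled; identical inputs, configuration and seed give
bit-identical results, and a saved YAML configuration plus the input CSV
reproduce an entire report. The package's own test suite exercises the
bootstrap at $b$ between 30 and 1000, the null-scenario error control at 200
replications of the 5 × 50 random challenge, and the consensus equivalence on
500 random tie-free profiles with up to 5 algorithms over 3 tasks — sizes at
which each property is already sharply testable while the suite stays fast.

## Worked example

```{r example, eval = FALSE}
library(benchrank)

data <- imputeMissing(generateIdeal(n = 50, seed = 1))
slice <- taskSlice(data)

ranks(aggregateThenRank(slice, "mean"))
#> A1 A2 A3 A4 A5
#>  1  2  3  4  5

br <- bootstrapRankings(slice, rankingMethod("meanThenRank"),
                        b = 1000, seed = 1)
all(br@tauDist == 1)
#> [1] TRUE

runReport(data, analysisConfig(b = 1000, seed = 1,
                               outputDir = "ideal-report"))
```

## Limitations

* Test-based ranking inherits the caveats of significance testing: lack of
  significance with few cases is not evidence of equivalence, and with many
  algorithms ties become frequent.
* The Wilcoxon–Nemenyi–McDonald–Thompson mean-rank alternative is
  deliberately not offered: its result for a pair changes when unrelated
  algorithms are added or removed.
* Consensus rankings weight tasks equally; weighted consensus is out of
  scope.
* Multi-metric single-task challenges are handled by relabeling metrics as
  tasks; there is no dedicated multi-metric schema.
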