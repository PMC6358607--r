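---
title: "Closed-loop differential evolution for media formulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop differential evolution for media formulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdde)
```

## The problem

Serum-free culture media are combinations of many supplements (cytokines,
small molecules, nutrients), each usable at several discrete doses. A
screen over 15 factors at up to 6 doses each spans on the order of
$6^{15} \approx 4.7\times10^{11}$ formulations — far beyond any factorial
design. `hdde` implements a closed-loop search for such spaces: an
adaptive differential-evolution (DE) engine proposes a batch of
formulations, the lab (or an in silico evaluator) measures replicate
viable-cell counts, and the engine feeds the responses back into
selection, so that a few hundred measured formulations suffice to find
media that rival a serum-containing positive control (PC).

The engine is deliberately phenotype-driven: it uses only the scalar
response (cell expansion), no mechanistic model, and it treats
measurement noise as a first-class citizen rather than an afterthought.

## The optimization loop

One *generation* is one propose–measure–select cycle over a population of
`NP = 3 D + extra` target formulations (`population_size()`; `D` factors,
`extra` fills residual plate capacity). A formulation is a length-`D`
vector of 0-based dose-level indices.

For each target $x_i$:

1. **Mutation** (rand/1): a donor $v = x_{r1} + F\,(x_{r2} - x_{r3})$ is
   formed on level indices treated as reals, with $r1 \ne r2 \ne r3 \ne i$
   drawn uniformly.
2. **Crossover** (binomial): each position takes the donor value with
   probability `CR`; one uniformly chosen position always takes the donor,
   so the trial differs from the target before quantization.
3. **Quantization**: coordinates are rounded to the nearest level (halves
   away from zero) and clipped to the grid. Rounding (rather than
   reflection) keeps the operator idempotent at the bounds and
   order-preserving.
4. **Evaluation**: the trial is measured with `replicates` wells — unless
   it is already in the evaluation library, in which case the stored
   replicates are reused and no well is spent. Trials identical to their
   target are counted carried-over without evaluation.
5. **Selection**: the trial displaces the target only if its replicate
   median is higher *and* a one-sided Wilcoxon rank-sum test rejects at
   level `alpha` (`select_winner()`). Ties retain the incumbent: under
   noise, an incumbent should only be unseated by evidence. With the
   default 3 replicates the smallest attainable one-sided exact p-value
   is $1/\binom{6}{3} = 0.05$, so `alpha = 0.10` is the default — any
   stricter level would make selection impossible at $n = 3$.

Replicate values entering selection are normalized by their own
generation's PC mean, which keeps reused library replicates comparable
across generations (plate-to-plate scale drift cancels).

### Scores, the library, and the candidate solution set

The performance score of a formulation is its mean response divided by
the mean PC response of the same generation, so the PC scores 1.0
(100%). Every measured formulation enters a deduplicating
**evaluation library** keyed by its level vector; `unique_count()` is the
number of distinct formulations ever measured and is the search's cost
meter.

The **candidate solution set** holds the best formulations encountered so
far (capacity `NP`). A newly measured formulation enters freely while the
set is below capacity; once full it must beat the weakest member by more
than `margin` times the estimated inter-experimental score SD
(`compete_best()`). That SD is pooled from formulations measured in two
or more generations; inside a pure simulation the library reuse rule
means no formulation is ever re-measured, so the estimate falls back to a
fixed 0.05 — in lab use, re-submitted formulations sharpen it.

### Clearing and root perturbation

After the schedule switches to exploitation (below), a **clearing**
(niching) step removes candidate-set members scoring below
`1 - clearing_fraction` (default 10%) of the best member. For each
cleared member a replacement is generated by `perturb_root()`: a
surviving root is chosen stochastically with score weights, its
single-factor, one-level neighbours are enumerated deterministically, and
one neighbour is drawn uniformly. Replacements overwrite the population
slots that held the cleared formulations (or the lowest-scoring slots),
so the population size is conserved and each replacement is measured in
the next generation. This concentrates the late-stage search in the
surviving high-score niches while never shrinking the population.

### Adaptive schedule and termination

The DE parameters start at `F = 1`, `CR = 0.5` and only ever decrease:

* `F` drops to 0.5 when the best candidate score has converged —
  relative change below `convergence_tol` (5%) over `convergence_window`
  (2) consecutive generation steps (`detect_convergence()`). Clearing
  activates at the same moment: both are exploitation moves.
* `CR` drops to 0.25 only after the `F` reduction, once on average at
  least `D/2` positions per target were unchanged between two consecutive
  generations.

The run terminates when (a) `max_generations` (default 25) is reached, or
(b) after the `F` reduction, at least 90% of the population is carried
over unchanged for `convergence_window` consecutive generations — with
the streak counted strictly in generations following the reduction.
Termination (b) can be disabled (`carried_termination = FALSE`) to trace
a full fixed-horizon performance curve, which is how the in silico
benchmark comparison is run; the closed-loop default keeps it on because
wet-lab generations cost a week of culture each.

The convergence statistic deserves a note: the detection quantity (best
candidate score) and the 5%/2-generation rule are this package's own
concrete choices for a step that closed-loop practice leaves
under-specified; they are exposed as `convergence_tol` and
`convergence_window` rather than hard-coded.

## In silico evaluators

Two evaluators stand in for the wet lab, each owning an independent
seeded RNG stream so that measurement noise and search stochasticity can
be varied separately.

**Noisy Rosenbrock benchmark** (`benchmark_landscape()`): level indices
map onto equally spaced coordinates in $[-2, 2]$ and the formulation is
scored by the min–max rescaled Rosenbrock value
$s(f) = (f_{\max} - \mathrm{rosen}(x_f)) / (f_{\max} - f_{\min})$, plus
Normal(0, `noise_sd` = 0.05) replicate noise. The exact grid extrema come
from `grid_extrema_chain_dp()` — the Rosenbrock sum couples only adjacent
coordinates, so a dynamic program over the chain finds the discrete
extrema in $O(D L^2)$ and the best grid point scores exactly 1.0, playing
the PC role. With 5 levels the grid contains the continuous optimum
$(1,\dots,1)$, so a 100% score is attainable. The rescaling turns the
classical minimization benchmark into the same maximize-relative-to-PC
convention the cell assays use. The noise magnitude is a package default
on the normalized score scale, configurable.

**Synthetic cell landscape** (`cell_landscape()`): replicate counts are
generated from exactly the log-scale quadratic model the post hoc
analysis assumes,
$$\log Y = K + G_p + \textstyle\sum_j \beta_j x_j +
\sum_{i<j} \beta_{ij} x_i x_j + \sum_j \beta_{jj} x_j^2 +
\varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),$$
with $x$ the coded doses in $[-1,1]$, $G_p$ a per-generation block
offset, and counts below a detection threshold reported *at* the
threshold with a left-censoring flag (the counting-sensitivity limit of a
cytometer). `random_cell_landscape()` draws a study-shaped coefficient
set: 3 strong main effects ($|\beta| \in [0.35, 0.55]$, one guaranteed
positive and dominant), weak residual mains $N(0, 0.05)$, two negative
quadratic (high-dose saturation) terms around $-0.2$, six weak
two-factor interactions ($|\beta| \le 0.12$), $\sigma = 0.2$ on the log
scale, $K = \log 10^5$ (a realistic well count), detection threshold
$e^{K-4}$, and PC log-mean $K + 0.8$. These defaults emulate the effect
structure repeatedly seen in media screens — one dominant factor,
saturation at high dose, many weak pairwise modulations — and they are
the fixed conditions under which the package's campaign-level tests run.

What the generator does *not* emulate: donor-to-donor biological
variability, day/edge plate effects beyond a scalar block offset,
responses that leave the quadratic family (thresholds, toxic cliffs), or
correlated replicate noise. Passing the in silico campaign tests
therefore demonstrates the control logic and statistics, not that any
particular wet-lab campaign will converge in as few generations.

## Similarity metrics

Two ordinal metrics on level indices (`hamming()`, `levenshtein_eq()`):
the Hamming distance counts factors at different dose levels; the
dose-step (Levenshtein-equivalent) distance sums absolute level
differences. For equal-length formulation vectors insertions and
deletions are meaningless, so the usual edit distance reduces to
substitutions weighted by dose discrepancy. Both are true metrics and
satisfy `hamming <= levenshtein_eq <= hamming * (L_max - 1)`. They are
computed on indices, not concentrations, because dose grids are
typically log-spaced — a one-step change is the natural unit.

## Post hoc quadratic analysis

After a campaign, the full evaluation library (excluding generation 1,
whose uniformly random population would otherwise dominate the design
with off-support points) is fitted by OLS to the quadratic model above
(`build_design()`, `fit_quadratic()`): natural-log response; coded doses;
all mains, squares and two-factor crossproducts; generation blocks as
fixed-effect indicator contrasts with the earliest retained generation as
reference. Three-factor and higher interactions are assumed negligible
and never fitted.

Left-censored counts are completed before fitting: a normal is fitted to
the log responses by censored maximum likelihood
(`fitdistrplus::fitdistcens()`), and each censored value is replaced by a
draw from the fitted normal truncated above at the log threshold
(`impute_censored()`). A single stochastic draw is the default (it
preserves response variance); a deterministic conditional-mean option
exists for exactly reproducible tables.

Coefficient p-values are Benjamini–Hochberg adjusted over the family of
factor-effect terms (mains + squares + crossproducts jointly; blocks and
intercept excluded, since the volcano display plots exactly that family),
and reported as logworth $=-\log_{10}(\text{FDR } p)$ with a strict
significance flag at FDR $p < 0.05$ (`volcano_table()`). Terms dropped
for collinearity are reported as aliased, never silently removed. The
natural-log base only rescales coefficients uniformly and is stated in
the output headers.

## Numerical and degenerate-input choices

* Quantization rounds halves away from zero, then clips; out-of-range
  donors land on the boundary level.
* Rank-sum tests are exact where tie-free; with ties the normal
  approximation is used and exact ties in the median retain the target.
* `total_combinations()` returns a double plus an exact decimal string
  (attribute `"exact"`), since the product exceeds the $2^{53}$ exact
  range of doubles for large spaces.
* A factor must have at least 2 levels; a zero dose is an ordinary grid
  point with no special-casing.
* Constant responses give zero effect estimates and undefined p-values,
  which are excluded from the BH family and never flagged significant.
* Checkpoints serialize the complete engine state (including the RNG
  stream) to JSON; a resumed run is bit-identical to an uninterrupted
  one.

## Problem sizes used by the test suite

The campaign-level tests run the 15-factor, 6-level synthetic campaign
and the 15-factor, 5-level benchmark at 10 seeds each, the 14-factor
NP=59 campaign at 10 seeds, and the coefficient-recovery study at 10
simulated campaigns of roughly 600 unique formulations (15 fixed-horizon
generations) — sizes chosen to mirror the wet-lab campaign scales while
keeping a full check run in a few minutes on one core. Oracle checks
(exhaustive rank enumeration, brute-force grid extrema, positional
distance re-counts) are exact and independent of the implementation they
verify.

## Known limitations

* Single scalar response; no multi-objective support.
* No surrogate-model acceleration: every proposal is measured (or
  reused), never predicted.
* The inter-experimental variability estimate used by
  `compete_best()` is only as good as the number of re-measured
  formulations; pure simulations always use the fallback.
* OLS on adaptively collected (non-orthogonal) libraries estimates
  coefficients consistently only under the assumed quadratic family;
  strong model misspecification biases the weak-effect estimates, and the
  volcano should be read as a screen, not as confirmatory inference.
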