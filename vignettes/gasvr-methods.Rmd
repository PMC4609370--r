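---
title: "Simultaneous SVR tuning and feature selection with a genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous SVR tuning and feature selection with a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

QSAR models predict a continuous molecular property — the motivating case
is log BB, the logarithm of the steady-state brain-to-blood concentration
ratio — from a table of computed descriptors. Two decisions dominate the
accuracy of a kernel model on such a table: which descriptors enter the
model, and which hyperparameters the kernel machine uses. The two are not
independent: the best kernel width for six descriptors is not the best
width for three hundred, and the best descriptor subset depends on how
flexible the kernel is allowed to be. Treating them as separate passes
(filter the features, then tune the parameters, or vice versa) therefore
searches a restricted slice of the joint space. `gasvr` searches the joint
space directly with a genetic algorithm.

## The model

The regression engine is epsilon-insensitive support vector regression
with the Gaussian radial-basis kernel

$$K(x_i, x_j) = \exp(-\gamma \lVert x_i - x_j \rVert^2), \qquad \gamma > 0,$$

whose fitted prediction function is the kernel expansion

$$f(x) = \sum_i (\alpha_i - \alpha_i^*)\, K(x_i, x) + b,$$

with dual coefficients bounded by the cost parameter,
$|\alpha_i - \alpha_i^*| \le C$. Three hyperparameters matter:

* **C** — the penalty on training residuals beyond the insensitive zone.
  Too large overfits (many support vectors), too small underfits.
* **gamma** — the kernel width; controls how locally the expansion bends.
* **epsilon** — the half-width of the zone within which residuals incur
  no loss. Larger epsilon selects fewer support vectors and flatter fits.

The quadratic program is solved by libsvm through `e1071::svm()`; the
package stores the support vectors, dual-coefficient differences, bias and
scaler, and its `predict()` method evaluates the expansion above directly.
A test asserts that the expansion and the solver's own predictions agree
to 1e-6, and that an independent solver (`kernlab::ksvm()`) run at tight
tolerance on the same fixture agrees to the same precision.

## The chromosome and the fitness

Each candidate solution is a mixed chromosome: three bounded float genes
$(C, \gamma, \varepsilon)$ concatenated with a feature gene — an array of
exactly `k_features` distinct integer indices into the descriptor table.
`k` is fixed within a run; model complexity is swept externally by
running the GA at several `k` values (`run_replicates()`).

Fitness is the mean squared error of k-fold (default 10) cross-validation
of the chromosome's SVR on the chromosome's features, pooled over all
held-out predictions:

$$\mathrm{MSE} = \frac{1}{n} \sum_{i=1}^{n} (\hat{X}_i - X_i)^2 .$$

Smaller is better. Two bookkeeping rules make this a clean objective:

* **Folds are fixed once per run**, drawn from the run seed, so fitness
  is a deterministic function of the chromosome within a run.
  Re-randomizing folds at every evaluation would turn selection into a
  race against fold noise.
* **Folds are keyed to sample identifiers**, not row positions: ids are
  sorted, shuffled with the seeded RNG, and cut into contiguous blocks.
  Reordering the rows of a table changes nothing. Within each fold the
  training rows are additionally fed to the solver in canonical id
  order, so the pooled CV error is exactly row-order invariant.
* **The feature scaler (z-score) is fit on each fold's training portion
  only** and applied to its held-out fold — no information leaks from
  the validation samples. Scaling is not optional in practice: raw
  descriptor columns span several orders of magnitude, and an RBF
  distance on raw scales is dominated by whichever column happens to be
  largest.

## The evolutionary operators

* **Selection**: tournament of 3 drawn with replacement; the candidate
  with the smallest CV MSE wins, ties to the first drawn. Tournament
  selection needs no global fitness sort and applies uniform selection
  pressure regardless of the fitness scale.
* **Crossover** (applied to a selected pair with probability
  `cross_rate`, default 0.8; otherwise the fitter parent is cloned):
  * float genes: blend crossover
    $V_{\text{new}} = \beta p_1 + (1 - \beta) p_2$ with $\beta$ uniform
    on $[-0.25, 1.25]$, drawn independently per gene; the extended
    interval lets children escape the parental segment, and results are
    clamped to the gene bounds.
  * feature gene: uniform crossover — a position-wise coin flip between
    the parents. Since both parents may carry an index at different
    positions, duplicates can arise; each duplicate slot is repaired by
    a uniform draw from the parents' unused indices (falling back to all
    unused indices), keeping offspring close to parental material.
* **Mutation** (each float gene and each feature slot independently with
  probability `mutation_rate`, default 0.1):
  * float genes mutate directionally:
    $V - \beta (V - V_{\min})$ downward or
    $V + \beta (V_{\max} - V)$ upward, a fair coin deciding the
    direction and $\beta$ uniform on $[0, 1]$ — the result cannot leave
    the bounds.
  * feature slots receive a uniform draw from the unused indices, so the
    gene always remains a set of distinct valid indices. When
    `k = N` there is no legal replacement and the gene is unchanged.
* **Elitism**: the `elite_size` (default 2) best individuals are copied
  unchanged, which makes the per-generation best fitness non-increasing
  — a property the tests assert on every run.
* **Immigrants**: `n_immigrants` (default 8) fresh random chromosomes
  are injected every generation to maintain diversity; they are part of
  the population budget, so each generation is assembled as
  `elite + immigrants + offspring = population_size`.

Defaults are population 100, 1000 generations, and the rates above; all
are configurable through `ga_config()`. The gene bounds default to
$C \in [0.01, 100]$, $\gamma \in [10^{-4}, 2]$,
$\varepsilon \in [0.001, 1]$ — wide enough to bracket the hyperparameter
values that k-fold tuning typically lands on for z-scored descriptor
tables (C of order 1–100, gamma below ~1, epsilon a modest fraction of
the response spread), and fully user-adjustable when a problem calls for
more room.

## Data preparation

`drop_unusable_features()` removes every column with a missing value
(no imputation — a descriptor that could not be computed for some
compound is simply not used) or with no variation. `clean_features()`
then removes near-duplicate columns: a single greedy pass over feature
pairs in column order drops one member — chosen by the seeded RNG — of
every pair with absolute Pearson correlation above the cutoff. The
default cutoff of 0.999999 is deliberately extreme: even strongly
correlated descriptors can be complementary in a nonlinear model, so
only effectively identical columns are removed. The pass handles
transitive blocks (three mutually identical columns leave exactly one
survivor) and is idempotent.

`kennard_stone_split()` selects a representative training set by maximin
coverage: the first pick is the sample closest to the feature-space
centroid, and every subsequent pick maximizes the minimum distance to
the already-selected set. Two conventions the procedure leaves open are
fixed as: distances are computed on z-scored features by default
(`standardize = FALSE` reverts to raw), the response is excluded from
the distance, and ties break to the lowest row index so the split is
deterministic and row-order stable. The test suite checks every
selection step against a brute-force maximin oracle on hundreds of
random small tables.

## The grid-search baseline

`grid_search()` is the conventional alternative the GA is compared
against: exhaustive evaluation of `cv_mse` over log2-spaced axes
(defaults $C: 2^{-5}..2^{15}$, $\gamma: 2^{-15}..2^{3}$,
$\varepsilon: 2^{-8}..2^{-1}$), on a fixed feature set, ties to the
first point in iteration order. Grid search cannot select features, so
its natural use is "all features, tuned parameters" — exactly the
baseline the acceptance study contrasts with the GA's "few features,
jointly tuned parameters".

## The synthetic benchmark

Real descriptor matrices come from proprietary pipelines and are rarely
redistributable, so the package ships a generator
(`synthetic_spec()` / `generate_table()`) that emulates their geometry
with known ground truth:

* binary indicator columns (Bernoulli 0.2), emulating structural flags
  such as a carboxylic-acid indicator;
* continuous columns built as unit-variance latents rescaled per column
  by a log-uniform factor spanning ~4 orders of magnitude — this forces
  the standardization machinery to matter, as it does on raw
  descriptors;
* planted blocks of near-duplicate columns and constant columns, so the
  cleaning rules can be tested against exact expected removal counts;
* a response that is a signed linear combination of the informative
  latents (binary columns contribute their 0/1 value), optionally with
  a smooth interaction term, plus Gaussian noise. Specifying
  `noise_frac` sets the noise sd as a fraction of the signal sd. The
  default effect signs follow the structure-permeability folklore the
  motivating application suggests: one positive lipophilicity-like
  effect, several negative polarity-like effects, one negative binary
  indicator.

The generator's defaults define the package's reference recovery
benchmark: 200 samples x 30 features, 3 informative columns (one the
negative binary indicator), noise sd at 10% of the signal sd.
`qsar_shaped_spec()` scales the same design to the 323 x 326 geometry of
the published log BB descriptor compilations, with planted duplicates
and constants whose cleanup leaves a table that a 260-sample
Kennard-Stone split divides 260/63.

What the generator does **not** emulate: correlations between moderately
related descriptors (real tables are full of r = 0.3–0.9 blocks, not
just near-exact duplicates), non-Gaussian descriptor distributions,
heteroscedastic or systematic measurement error, and any actual
structure-property physics. Passing the recovery benchmark therefore
shows that the search machinery finds planted signal under realistic
scale heterogeneity and noise — it does not certify accuracy on any
particular real descriptor set.

## Numerical choices

* **Solver tolerances.** Fitness evaluations during the search use a
  relaxed libsvm termination tolerance (0.01, `fit_tolerance` in
  `ga_config()`); final refits and reported models use the solver
  default (0.001). Coarse-search/fine-refit is standard practice: the
  search only needs fitness values accurate enough to rank chromosomes,
  and the relaxation roughly tolerance-bounds the solve time of
  high-cost chromosomes. All numbers reported by `summary()`,
  `evaluate_final_model()` and the acceptance script come from
  default-tolerance fits of the *selected* chromosome.
* **Fitness caching.** Within a run, fitness values are memoized on the
  chromosome (features compared as a set), so elites and unmutated
  clones are never re-evaluated.
* **Degenerate inputs.** Constant responses fit to a constant model
  within epsilon; all-identical training rows must not crash (the solver
  returns a constant model); zero-spread columns inside a CV fold get
  scale 1 rather than dividing by zero.
* **Tie-breaks.** Kennard-Stone ties to the lowest row index; tournament
  ties to the first drawn; grid ties to the first point in iteration
  order; frequency tables order ties by ascending feature index. Every
  tie rule is deterministic so that end-to-end runs are byte-identical
  under a repeated seed.
* **Seed discipline.** A run's seed drives the fold assignment, the
  initial population and every operator draw, through a seed-scoped RNG
  that restores the caller's stream. `run_replicates()` derives per-run
  seeds as `seed + 1000 k + run`.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to keep a complete
run on a single CPU comfortable while remaining honest about the
method's behavior: the recovery benchmark runs 10 replicates at
population 30 for 100 generations (about 2,500 fitness evaluations per
replicate); the exhaustive feature-triple oracle evaluates all
C(30,3) = 4060 subsets; the brute-force Kennard-Stone oracle checks 200
random tables; operator closure is checked on 1e5 random cases. The
descriptor-scale defaults (population 100, 1000 generations, 50
replicates per k, k swept 4–15) are what one would use on a real
descriptor table on a workstation.

## Known limitations

* The GA optimizes CV MSE on whatever table it is given; if model
  selection and final evaluation must be independent, run the search on
  the training partition of a `kennard_stone_split()` and report
  held-out metrics via `evaluate_final_model()` (this is what
  `run_replicates(..., split = )` automates).
* `k_features` is fixed per run by design; subset size is a sweep
  variable, not a gene. Variable-length genomes and multi-objective
  fitness (accuracy vs complexity) are out of scope.
* Squared-Pearson r² (the QSAR reporting convention, and this package's
  default) rewards correlation, not calibration; `r_squared(...,
  method = "cod")` gives the coefficient of determination when bias
  matters.
* Wrapper selection on small tables can overfit the CV criterion
  itself; the occurrence analysis across replicates
  (`feature_frequency()`) is the intended antidote — trust features
  that recur, not any single run's subset.
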