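---
title: "Chaotic antlion optimization for wrapper feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaotic antlion optimization for wrapper feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caloFS)
```

## The optimization model

`caloFS` treats feature selection as continuous minimization over the unit
hypercube $[0,1]^{N_t}$, one dimension per feature. A population of $N$
*ants* explores the cube; a second population of *antlions* retains good
solutions and shapes where the ants walk. Each iteration $t \le T$
proceeds, for every ant:

1. **Trap selection.** An antlion is drawn by roulette wheel. Fitness is
   minimized, so selection weights are max-shifted:
   $w_j = \max_i f_i - f_j + \varepsilon$ with $\varepsilon = 10^{-12}$.
   The shift makes better (lower) fitness strictly more probable whenever
   fitnesses differ and degrades to a uniform draw when they are all equal;
   $\varepsilon$ only prevents a zero-weight vector.
2. **Bound shrinking.** The global bounds are divided by the exploration
   ratio $I$ (below), then centred on the guiding antlion. Each bound's
   sign is flipped with probability $1/2$ before translation, so the walk
   interval may lie on either side of the guide — the trap is a
   neighbourhood *around* the antlion, not a half-space. This flip is
   load-bearing: with the feature-selection domain $[0,1]$ the shrunken
   lower bound is $0/I = 0$, and without the flip every interval would sit
   entirely above the guide, coordinates could never decrease once the
   population converges, and features could never switch off. We observed
   exactly that failure mode (inflated subsets, exhaustive optimum never
   reached) before adopting the flip, which also matches the reference
   implementation of the base algorithm.
3. **Random walks.** For each guide (the selected antlion and the elite)
   and each dimension, a fresh $T$-step unit random walk is generated
   (step $+1$ if a uniform draw exceeds $0.5$, else $-1$, cumulatively
   summed from 0) and min–max normalized into the shrunken, centred
   interval; the entry at index $t$ is the walk value used. Regenerating
   the walk each iteration keeps the normalization well defined at every
   $t$ and follows the reference implementation. The walk equation's
   printed normalization uses inconsistent sub/superscripts in the
   literature; we adopt the standard min–max reading
   $X' = (X - \min X)(d_i - c_i)/(\max X - \min X) + c_i$. The elite's walk
   bounds are shrunk by the same ratio as the selected antlion's.
4. **Repositioning.** The ant moves to the mean of its two walk values,
   clipped (not reflected) into the global domain — the simplest total
   contract, and immaterial here because positions are only ever
   thresholded.

After all ants move: each antlion absorbs its ant if the ant is *strictly*
fitter (ties leave the antlion unchanged, avoiding position churn without
fitness gain), and the elite is updated to the best antlion. The elite
fitness trace is therefore non-increasing by construction — a property the
test suite asserts across schedules and seeds.

## The exploration schedule and its chaotic modulation

The base ratio is $I = 10^w\, t/T$ with $w$ stepping through
$2, 3, 4, 5, 6$ as $t/T$ crosses $0.1, 0.5, 0.75, 0.9, 0.95$. Below
$0.1\,T$ the table assigns no $w$; we set $I = 1$ there (no shrinking),
matching the base algorithm's fully exploratory opening phase.

The quasi-linear growth of $I$ spends the first half of the budget
exploring and the rest exploiting, which can converge prematurely or
stagnate in local minima. The chaotic variant advances a chaotic map once
per optimizer iteration (not per ant — the schedule is a per-iteration
quantity) and couples its value $x_t \in (0,1)$ to the ratio as

$$\hat I_t = \max(1,\ I_t^{x_t}).$$

No closed form for this coupling is established in the literature we build
on; the exponent form is our design choice because it reproduces the
intended behaviour exactly: $x_t \to 0$ gives $\hat I_t \to 1$ (full
exploration), $x_t \to 1$ recovers the base envelope $I_t$, and
$\hat I_t \in [1, I_t]$ always, so the chaotic schedule alternates
exploration and exploitation *within* the base envelope rather than
overriding it. An envelope-free alternative (`coupling = "replace"`,
$1/\hat I_t = x_t$) is provided for sensitivity checks.

Five maps are supported (defaults in parentheses): logistic ($a = 4$),
sinusoidal ($a = 2.3$), tent, singer ($\mu = 1.07$), piecewise
($p = 0.4$), all iterated from $x_0 = 0.7$. The logistic and sinusoidal
multipliers are the standard chaotic operating points; the singer and
piecewise parameters and $x_0$ are not fixed by the literature, so we
chose mid-range values inside the maps' chaotic ranges and expose all of
them as arguments. Two boundary conventions are pinned down explicitly:
the tent map at exactly $x = 0.7$ takes the second branch (0.7 is that
branch's fixed point), and logistic initial conditions in
$\{0.25, 0.5, 0.75\}$ are rejected at construction because their orbits
provably collapse to 0 (e.g. $0.5 \to 1 \to 0$).

## The wrapper objective

A position binarizes at the static threshold $0.5$ (the value $0.5$ itself
selects). The mask's fitness is

$$\alpha\,(1 - P) + (1 - \alpha)\,N_f/N_t,$$

with $P$ the accuracy of $k$-NN ($k = 5$) trained on the training third
and evaluated on the validation third. The weight $\alpha = 0.99$ makes
accuracy dominant while still breaking accuracy ties toward smaller
subsets; it is exposed as `alpha`. The empty mask returns fitness 1 (the
worst value) instead of raising, keeping the objective total over the
cube. Features are min–max scaled with training-split statistics before
distance computation so differently-scaled features contribute comparably;
zero-range features scale to 0. KNN ties are deterministic: equal
distances prefer the lower training-row index (stable ordering), tied
votes fall back to the single nearest neighbour's label. These tie rules
are why the classifier is implemented in the package rather than delegated
— off-the-shelf KNN implementations break ties randomly, which would
destroy seed-reproducibility; an independently coded brute-force KNN
cross-checks it in the tests.

Each dataset is split into stratified equal thirds (training, validation,
test): within each class, shuffled indices are dealt into three sets of
equal size within one sample. Stratification is our choice — plain
shuffling can empty a small biomedical class out of a split. The test
third is used exactly once per run, to report the selected subset's
accuracy.

The full-feature position is forced into both initial populations of every
run. Since the elite starts no worse than that agent and the trace is
non-increasing, every returned subset is guaranteed at least as fit as
using all features.

## Evaluation metrics

Over $M$ independent runs the package reports the mean, best (min), worst
(max) and standard deviation (sample, $1/(M-1)$; undefined and reported
`NA` at $M = 1$) of the per-run best fitness; the mean test accuracy; the
mean selected fraction $N_f/N_t$; and the Fisher score. The Fisher score
of feature $j$ is computed as printed in the formulation we implement:
$F_j = \sum_k n_k(\mu_{kj} - \mu_j)^2 / \sigma_j^2$ with $\mu_j$ and
$\sigma_j$ taken over the *entire* dataset — note this differs from the
classical within-class-variance Fisher score. The variance uses the
population convention (divisor $N$); the convention is not fixed by the
formulation, so we chose one and hold it constant (the score's affine
invariance and $n_k$ scaling are tested numerically). The per-run
aggregate is the *sum* of $F_j$ over the run's selected features, averaged
over runs; a per-feature mean is available via `aggregate = "mean"`.

## The synthetic generator and what passing tests mean

`generate_synthetic()` emulates the structure of small biomedical
classification datasets: balanced classes, `n_informative` dimensions
drawn from class-conditional normals with consecutive class means
separated by `delta * sigma`, and `n_noise` dimensions identically
distributed across classes, with the informative columns at seeded random
positions and their indices returned as ground truth. It does **not**
emulate feature correlation, heavy tails, label noise, missing values or
class imbalance (imbalance only via unequal `n_samples` rounding), so
passing tests demonstrate correct optimizer and metric behaviour on
well-separated Gaussian structure, not performance on real clinical data.

One interaction deserves emphasis because it is a property of the fitness,
not a bug: with strong separation (`delta = 3`) a small subset of the
planted features already classifies perfectly, and the fitness then
*strictly prefers* that subset to the full planted set (e.g.
$0.01 \cdot 2/20 < 0.01 \cdot 5/20$ at perfect accuracy). A correct
optimizer therefore prunes redundant informative features: recall of the
planted set saturates well below 1 while precision stays high. Recovery
experiments on such data should expect minimal perfect subsets, not the
full planted set.

The exhaustive oracle enumerates all $2^{N_t} - 1$ nonempty masks (capped
at 15 features, i.e. 32767 evaluations) and resolves fitness ties toward
the lexicographically smallest mask, giving a deterministic ground-truth
optimum against which optimizer runs are checked (they can match it, never
beat it).

## Defaults, problem sizes and numerical choices

* Population 8, iterations 70, $\alpha = 0.99$, $k = 5$, threshold 0.5,
  domain $[0,1]$ — the standard operating point of this method family for
  feature selection; $M = 20$ runs by default in `run_experiment()`, with
  per-run seed = base seed + run index so runs are independent yet
  reproducible, and the whole report is a deterministic function of
  (config, seed).
* Validation experiments in the tests and acceptance script use synthetic
  datasets of 150–600 samples and 10–20 features (the oracle-checked
  problem uses 10 features so all 1023 masks can be enumerated), and a
  five-dataset stability suite spanning $n = 240$–$450$, 10–20 features
  and separations $\delta = 1$–$3$ — a realistic difficulty spread from
  strongly separated to substantially overlapping classes, at sizes typical
  of the small clinical tabular datasets this method targets.
* Floating-point: normalized walks are clamped to their target interval to
  absorb rounding at the boundaries; chaotic iterates are clamped to
  $[0,1]$ (the recurrences are analytically inside); fitness comparisons in
  tests use $10^{-12}$ slack where exact mask identity is not implied.
* Degenerate inputs have pinned behaviour: constant walks normalize to the
  interval midpoint, $k$ larger than the training set clamps with a
  warning, zero-variance features score Fisher 0 with a warning, an empty
  mask scores fitness 1, and a run whose best mask is somehow empty
  predicts the training majority class at test time.

## Known limitations

The optimizer wraps a single classifier (KNN); fitness landscapes under
other classifiers may rank subsets differently, and run time scales with
classifier training cost. Selected subsets are not unique across runs —
repeated applications can return different, equally fit subsets, which is
inherent to the stochastic search and the reason the stability (standard
deviation) metric exists. The generator's independence assumptions make
synthetic problems easier than correlated real data; conclusions about
relative optimizer performance transfer better than absolute accuracies.
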