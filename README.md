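# caloFS — chaotic antlion optimization for wrapper feature selection

Biomedical datasets routinely describe each sample with far more measured
features (biomarkers, clinical attributes) than are needed to classify it,
and many of those features are noisy or redundant. `caloFS` addresses the
wrapper formulation of feature selection: search the space of feature
subsets for one that keeps classification accuracy high while using as few
features as possible, judging every candidate subset by the performance of
a classifier actually trained on it.

## The method

The search engine is the **antlion optimizer (ALO)**, a swarm method in
which a population of *ants* (candidate solutions) random-walk inside traps
built by a population of *antlions* (retained good solutions). At iteration
*t* of *T*, each ant walks around a roulette-selected antlion and around the
best antlion found so far (the *elite*), and moves to the average of the two
walks. The walk bounds shrink over time by the exploration ratio

> I = 10^w · t/T,  with w stepping through 2, 3, 4, 5, 6 as t/T crosses
> 0.1, 0.5, 0.75, 0.9, 0.95 (I = 1 before 0.1·T),

handing the search over from exploration to exploitation quasi-linearly.
The **chaotic variant (CALO)** replaces that monotone hand-over with
alternating phases: a chaotic map (logistic, sinusoidal, tent, singer or
piecewise) is advanced once per iteration and its value x_t ∈ (0,1)
modulates the ratio as Î = max(1, I^{x_t}), so the effective rate swings
between full exploration (x_t → 0) and the base exploitation envelope
(x_t → 1).

For feature selection the search space is [0,1]^{N_t}; a position is
thresholded at 0.5 into a feature mask, and the mask is scored with the
minimized bi-objective fitness

> fitness = α · (1 − P) + (1 − α) · N_f / N_t,

where P is the accuracy of a k-nearest-neighbour classifier (k = 5)
trained on the training third of the data and evaluated on the validation
third, N_f is the number of selected features, and α = 0.99 weights
accuracy against subset size. The test third is touched only for final
reporting. The all-features position is forced into every initial
population, so the returned subset is never worse than using every
feature. Repeated runs are summarized with the usual suite: fitness
mean/best/worst/standard deviation, average test accuracy, average
selection size, and the Fisher score of the selected features.

The package also ships a synthetic-data generator with planted informative
features (class-separated Gaussian dimensions plus pure-noise dimensions)
and an exhaustive-search oracle for feature spaces up to 15 dimensions, so
every claim about the optimizer can be checked against ground truth.

## Worked example

Ten features, of which three (columns 2, 8, 10) carry signal; ALO vs
CALO with the tent map, 10 independent runs each:

```r
library(caloFS)
d <- generate_synthetic(n_samples = 300, n_informative = 3, n_noise = 7,
                        delta = 3, seed = 11)
d$informative
#> [1]  2  8 10
ex <- run_experiment(d$x, d$y, optimizers = c("alo", "calo-tent"),
                     runs = 10, seed = 11)
ex
#> <calo_experiment> 10 runs x 2 optimizers (8 agents, 70 iterations, seed 11)
#>   optimizer runs failed mean_fitness best_fitness worst_fitness std_fitness
#> 1       alo   10      0       0.0025        0.002         0.003    0.000527
#> 2 calo-tent   10      0       0.0020        0.002         0.002    0.000000
#>   avg_accuracy avg_selection_size avg_fisher
#> 1        0.974               0.25        411
#> 2        0.974               0.20        411
```

The exhaustive oracle over all 2^10 − 1 = 1023 masks confirms what the
optimizer found:

```r
sp <- three_way_split(d$x, d$y, seed = 11)
exhaustive_oracle(sp)
#> $fitness 0.002   $mask 0000000101
```

Fitness 0.002 = 0.99·(1 − 1) + 0.01·(2/10): two features (both planted)
classify the validation third perfectly. CALO-tent attains that optimum in
all ten runs (std 0 — it converges to the same solution every time), the
base schedule in some; both retain high test accuracy (0.974) with a
fraction of the features. `write_report(ex, "report.csv")` saves the table
plus a provenance sidecar with seeds and per-run masks.

The same experiment from a shell:

```sh
cli=$(Rscript -e 'cat(system.file("cli/calo", package = "caloFS"))')
Rscript $cli synth --spec 300,3,7,3 --seed 11 --out data.csv
Rscript $cli run --data data.csv --optimizer alo,calo-tent --runs 10 \
        --seed 11 --out report.csv
```

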