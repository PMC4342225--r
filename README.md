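# wrapfs

Genetic-algorithm wrapper feature selection for biomedical classification,
with information-theoretic filter pre-selection and a nested
cross-validation assessment harness.

## The problem

High-dimensional biomedical data (sequence windows, microarrays,
transcription-factor interaction tables) carry many features that are
irrelevant to the class being predicted. *Wrapper* feature selection scores
candidate feature subsets by the cross-validated performance of an actual
classifier trained on them — capturing feature interactions that univariate
statistics miss — and wrapfs implements the standard GA-driven form of it
for anyone who needs compact, well-performing feature panels from
tab-delimited sample-by-feature tables.

## The model

A subset is a binary chromosome θ over the n candidate features. A
single-population genetic algorithm (population 100, two-point crossover at
rate 0.8, bit-flip mutation at rate 0.01, elitist generational replacement,
steady-state stop after 50 stagnant generations) maximizes the
size-penalized fitness

    fitness(θ) = Performance(θ) − α · sum(θ)/n,        α = 0.15

where Performance is the inner 5-fold cross-validated metric (GMean,
accuracy, F1 or MCC) of the wrapped classifier — an in-house Gaussian naive
Bayes, k-nearest neighbours, or the mean of both. For large n, a greedy
information-theoretic filter (mRMR, JMI, CMIM or ICAP; plug-in mutual
information on 10 equal-frequency bins) first retains the top 10% of
features and the GA searches within them. `nested_cv()` assesses any method
leakage-free, reporting the seven confusion-matrix metrics, the reduction
percentage, and the chance-corrected selection stability

    S(θi, θj) = (c − ki·kj/n) / (min(ki, kj) − max(0, ki + kj − n))

averaged over outer-fold pairs (range (−1, 1], 0 under random selection).

## Worked example

Fifty features, of which five are informative, on 300 samples:

```r
library(wrapfs)

sim <- make_informative_dataset(n_samples = 300, n_informative = 5,
                                n_noise = 45, seed = 42)
ga <- run_ga(sim$data, ga_config(population_size = 40, max_generations = 30,
                                 stagnation_patience = 15, seed = 1))
ga
#> GA wrapper feature selection: 11 of 50 candidate features selected
#>   best fitness 0.8458 (performance 0.8788), stopped by max_generations after 30 generations
sort(ga$selected)
#>  [1]  1  2  3  4  5 22 25 28 30 33 43
```

The best mask keeps all five informative features (indices 1–5) plus six
noise features; its inner-CV GMean is 0.879 and the fitness subtracts
0.15 × 11/50 = 0.033 for the mask size. `tidy(ga)` returns the
per-generation history, `autoplot(ga)` draws the fitness trajectory.

The full nested assessment of a filter method on the same data:

```r
cv <- nested_cv(sim$data, method = "mrmr", seed = 1)
cv
#> Nested 5-fold cross-validation (method: mrmr, classifier: nbc)
#>   sensitivity    0.807 +/- 0.072
#>   specificity    0.853 +/- 0.096
#>   ppv            0.852 +/- 0.085
#>   gmean          0.828 +/- 0.059
#>   f1             0.826 +/- 0.060
#>   accuracy       0.830 +/- 0.059
#>   mcc            0.665 +/- 0.120
#>   reduction_pct 10.000 +/- 0.000
#>   mean stability 0.760
```

Each line is the mean ± sd of the outer-fold test metrics; `reduction_pct`
says the filter kept 10% of the features in every fold, and the stability
of 0.76 means the five folds selected substantially overlapping subsets
(0 would be chance-level agreement). `tidy(cv)` and `glance(cv)` give the
per-fold and one-row summaries.

Tab-delimited tables (samples in rows, label in the last column) are read
with `read_feature_table()`; `inst/scripts/wrapfs.R` is a thin command-line
front end over `run_from_config()` with subcommands `filter`, `select`,
`evaluate`, `simulate` and `sweep`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the difference between
the wrapped classifier's Performance and the Eq.-style fitness of the
all-ones chromosome under the default penalty weight, and the mean pairwise
stability of 1000 uniformly random subset pairs (n = 100 features, sizes
5–50), writing both as JSON.
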