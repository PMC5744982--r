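# sblogit

Sparse Bayesian logistic regression with **correlated** feature
selection, for binary classification of expression data.

## The problem

Classifiers built on expression profiles (microarray, RNA-seq, protein
panels) are used both to predict sample groups and to nominate the
features they rely on as biomarker candidates. Standard embedded
selectors — l1-penalised logistic regression, relevance-vector (sparse
Bayesian) classification — keep only one representative out of a group
of highly correlated informative features. Co-regulated genes are
exactly such groups, and the dropped members are what downstream
pathway/enrichment analysis needs.

`sblogit` fits a logistic model under per-feature Gaussian priors
(automatic relevance determination),

```
P(y=1|x) = S(β'x),   S(f) = 1/(1+e^{-f}),   β_i ~ N(0, γ_i),
```

estimating `β` and the prior variances `γ` jointly by minimising the
Laplace-approximate negative log marginal posterior

```
J(β,γ) = Σ_n log(1+exp(-y_n β'x_n)) + ½ β'Γ⁻¹β + ½ log|Γ| + ½ log|H(β)|
```

via a convex–concave (reweighted-ridge) iteration: each round solves a
weighted ridge-logistic problem with weights `w_i = 1/γ_i` (L-BFGS),
then updates `α_i = 1/γ_i − [H⁻¹]_ii/γ_i²` and `γ_i = |β_i|/√α_i` in
closed form, pruning features whose variance collapses. Because the
quadratic penalty splits weight across near-duplicate columns instead of
thresholding them, correlated informative features are retained
*together*, with same-sign weights.

The package also provides the two standard comparators behind the same
interface (`l1logit()`: ADMM l1-logistic; `rvmlogit()`: constructive
relevance-vector classification), a seeded simulation generator with
correlated feature pairs, and an evaluation layer (stratified CV with
embedded per-fold selection, FP/FN rates against simulation truth, a
stability/accuracy score with an optimal feature-set-size search).

## Worked example

```r
library(sblogit)
sim <- simulate_correlated_design(n_samples = 500, n_features = 50,
                                  support_size = 8, seed = 7)
fit <- sblogit(sim$x, sim$y)
summary(fit)
#> sparse Bayesian logistic regression (reweighted ridge)
#>   500 samples, 50 features
#>   support size: 8; iterations: 5 (converged)
#>   final joint objective (Laplace scale): 25.8543
#>   selected features (by |weight|):
#>   feature index weight
#> 1      f9     9 -8.715
#> 2      f3     3 -7.783
#> 3      f4     4 -6.537
#> 4     f29    29 -6.514
#> 5     f31    31 -6.193
#> 6     f47    47 -6.000
#> 7     f18    18 -4.804
#> 8     f35    35 -3.642

sim$truth$support
#> [1]  3  4  9 18 29 31 35 47

cv_accuracy(sim$x, sim$y, "sblogit", folds = 10, seed = 8)
#> [1] 0.994
```

The eight selected features are exactly the eight true ones — including
*both* members of each of the four correlated pairs (sample correlation
≈ 0.995) — and the pooled 10-fold CV accuracy is 0.994. On the same
data, `l1logit()` and `rvmlogit()` keep only one member of most pairs;
`select_q()` shows their stability/accuracy score peaking near 4
selected features, against 8 for `sblogit()`.

Real expression matrices come in through
`read_expression_matrix(matrix_tsv, labels_tsv, transpose = TRUE)`
(genes-in-rows input), and fits go out through `write_fit_report()`
(ranked weights TSV plus a run-metadata JSON). A thin command-line
wrapper with `simulate` / `fit` / `cv` subcommands ships in
`inst/cli/sblogit-cli.R`.

See the vignette (`vignettes/sparse-bayes-logistic.Rmd`) for the model,
the solver's design decisions, and the evaluation protocol.

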