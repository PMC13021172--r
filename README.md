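# sgadt

Adaptive imputation of missing values in tabular classification data by
genetically tuned support vector regression, followed by an interpretable
CART decision tree — plus the benchmarking harness to compare it against the
standard missing-data treatments.

## The problem

In clinical tables (breast-cancer recurrence records, mammographic mass
descriptors, hepatitis panels, ...) missing entries concentrate in the
predictor attributes. Deleting incomplete rows discards signal and biases
the sample; filling with a column mean ignores the inter-attribute
dependencies that make recovery possible. And whatever completes the table
must feed a classifier a clinician can audit.

## The method

For each incomplete non-class attribute with missing fraction λ, the
imputation strategy is dispatched by regime (thresholds τ₁ = 0.10,
τ₂ = 0.25):

| regime | λ | strategy |
|---|---|---|
| low | λ ≤ τ₁ | single-pass epsilon-SVR on correlation-filtered predictors |
| medium | τ₁ < λ ≤ τ₂ | iterative SVR: refit with previous estimates until stable |
| high | λ > τ₂ | KNN bootstrap (mean / majority of k nearest donors), then SVR refinement |

Predictors with Pearson ρ ≤ 0 against the target (over mutually observed
rows) are filtered out. The SVR kernel and hyperparameters — kernel ∈
{linear, RBF, polynomial}, C ∈ [0.1, 1000], ε ∈ [0.001, 1], γ ∈ [1e-5, 10],
degree ∈ {2..5} — are chosen per attribute by a genetic algorithm
(tournament selection of size 2, uniform + blended crossover at 0.8,
per-gene mutation at 0.1, elitism) minimizing the 5-fold cross-validated
imputation MSE. The completed table is classified by a binary CART tree
(Gini splitting, GI = 1 − Σ pᵢ²) with minimal cost-complexity pruning, and
the tree exports one plain-text rule per leaf.

The package also ships the seven baseline imputers (drop, mean, mode,
median, KNN, linear regression, neural network), a canonical un-tuned SVR
baseline, calibrated MAR missingness injection, latent-factor synthetic data
generators with known ground truth, and a stratified, leakage-audited
cross-validation harness with a missingness sweep (10–50%).

See `vignettes/adaptive-imputation.Rmd` for the full model description and
design rationale.

## Worked example

```r
library(sgadt)

# a synthetic table with known ground truth: 300 rows, 6 numeric
# attributes, ~20% MAR missingness in x02..x06 driven by the held-out,
# fully observed x01
sd <- gen_numeric(synthetic_spec(n = 300, n_numeric = 6, rate = 0.2,
                                 seed = 7))
print(sd$masked)
#> <sga_dataset> 300 rows x 7 attributes (6 predictors + class 'class')
#>   missing cells: 310 (17.2% of predictor cells)

# adaptive GA-optimized imputation
res <- impute_dataset(sd$masked,
                      ga = ga_config(pop_size = 10, generations = 6,
                                     patience = 3, seed = 1))
res$diagnostics[, c("attribute", "lambda", "regime", "strategy",
                    "kernel", "C", "cv_mse")]
#>  attribute    lambda regime      strategy kernel          C    cv_mse
#>        x05 0.1833333 medium iterative_svr linear  0.1197581 0.4125664
#>        x04 0.2033333 medium iterative_svr   poly 47.2644250 0.3526778
#>        x06 0.2100000 medium iterative_svr linear  0.1000000 0.4349733
#>        x02 0.2133333 medium iterative_svr   poly 99.9072492 0.2919223
#>        x03 0.2233333 medium iterative_svr linear 31.0902164 0.3034533

# how close are the imputed cells to the pre-mask truth?
imputation_rmse(res, sd$truth, sd$masked$mask)
#>      rmse cat_error
#> 0.6654828        NA
imputation_rmse(baseline_impute(sd$masked, "mean"), sd$truth,
                sd$masked$mask)
#>     rmse cat_error
#>  1.035929        NA

# classify the completed table with a pruned CART tree
tree <- ccp_prune(induce_tree(res$dataset), alpha = 0.01)
head(export_rules(tree), 3)
#> [1] "IF x01 <= 0.155304 AND x03 <= 0.246182 THEN class = 0  [counts = 106/14, gini = 0.206]"
#> [2] "IF x01 <= 0.155304 AND x03 > 0.246182 AND x05 <= -1.11762 THEN class = 0  [counts = 7/0, gini = 0.000]"
#> [3] "IF x01 <= 0.155304 AND x03 > 0.246182 AND x05 > -1.11762 THEN class = 1  [counts = 6/29, gini = 0.284]"
```

Reading the output: per attribute, `lambda` is the realized missing
fraction; all five incomplete attributes fall in the medium regime (10-25%),
so the iterative strategy was dispatched. `cv_mse` is the cross-validated
MSE of the GA-selected SVR configuration -- the per-attribute kernels
differ, which is the point of the kernel-aware search. The imputed cells
land at roughly 64% of the root-mean-square error of mean filling on the
same masked cells (0.67 vs 1.04). Each tree rule reports its leaf's class
counts and Gini impurity: the first leaf with counts 106/14 has
GI = 1 - (106/120)^2 - (14/120)^2 = 0.206.

Benchmarking frameworks on identical folds:

```r
cmp <- compare_frameworks(sd$masked, c("drop", "mean", "knn", "svr"),
                          k = 5, seed = 1)
cmp$summary
#>  framework  accuracy precision    recall f_measure
#>       drop 0.8228753 0.8120979 0.6966667 0.7384980
#>       mean 0.7461684 0.7568233 0.7641129 0.7592339
#>        knn 0.7597786 0.7728384 0.7711694 0.7703629
#>        svr 0.7863416 0.8147598 0.7774194 0.7930507
```

(`drop` scores are computed only over the test rows that survive deletion;
at these modest missingness levels the surviving third of the rows happens
to be the easy, fully consistent subset, which inflates its accuracy while
its recall -- the lowest of the four -- shows the deletion penalty.)

## Command line

A thin front-end over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "sgadt.R", package = "sgadt"))') \
    impute --input data.csv --class-col outcome --seed 1 --out out/
```

Commands: `impute`, `classify`, `benchmark`, `sweep`, `synth`; flags include
`--dialect` (csv or KEEL), `--tau1/--tau2`, `--k`, `--ccp-alpha`, `--folds`,
`--levels`, and a mandatory `--seed`.

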