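---
title: "Adaptive SVR imputation with genetic kernel search and CART classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive SVR imputation with genetic kernel search and CART classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgadt)
```

## The problem

Clinical and epidemiological tables routinely arrive with missing entries in
the predictor (non-class) attributes — skipped laboratory tests, unrecorded
BI-RADS descriptors, incomplete questionnaires. Deleting incomplete records
wastes information and biases the sample; naive statistical fills (mean,
median, mode) ignore the dependencies between attributes that carry most of
the recoverable signal. `sgadt` implements an adaptive pipeline for this
setting: each incomplete attribute is imputed by epsilon-insensitive support
vector regression (SVR) on its correlated peers, with the imputation
*strategy* chosen by how much of the attribute is missing and the SVR
*configuration* chosen by a genetic algorithm; the completed table is then
classified by a CART decision tree whose rules remain readable by a
clinician.

## The model

### Missingness regimes and strategy dispatch

For an attribute with missing fraction $\lambda$, the imputation function is
selected as

$$
f = \begin{cases}
\text{standard SVR} & \lambda \le \tau_1\\
\text{iterative SVR} & \tau_1 < \lambda \le \tau_2\\
\text{KNN-initialized SVR refinement} & \lambda > \tau_2
\end{cases}
$$

with defaults $\tau_1 = 0.10$ and $\tau_2 = 0.25$. The boundaries are closed
from below: an attribute at exactly $\tau_1$ is *low*. Dispatch is
per-attribute; the dataset-level share of rows with at least one missing
cell is reported by `missingness_profile()` as a summary only. The
rationale: below ~10% missingness the observed dependency structure is
essentially intact and a single regression pass suffices; between 10% and
25% the holes in the *predictor* columns start to matter, so the fit is
repeated with the previous round's estimates standing in until the imputed
values stabilize; above 25% there is too little complete structure to train
on directly, so a k-nearest-neighbour pass first makes the table
structurally complete and SVR then refines the rough local estimates with a
global model.

### Predictor filtering

Candidate predictors for a target attribute are the other non-class
attributes, scored by the Pearson correlation with the target over mutually
observed rows; candidates with $\rho \le 0$ (or undefined $\rho$, e.g.
constant columns) are removed (`correlation_filter()`). When nothing
survives — a possibility the dispatch rule has to face on anti-correlated
data — the three candidates with the largest $|\rho|$ are retained and the
event is flagged in the diagnostics, because the regressor needs at least
one input. Negative correlations are informative in principle; the filter
follows the framework's published rule, and the fallback confines the damage
on adversarial inputs.

### The SVR stage

`fit_svr()` wraps the libsvm epsilon-regression solver (via `e1071::svm`).
Predictors *and* the response are standardized on the training rows inside
the wrapper, so the hyperparameter ranges below refer to a standardized
scale, and predictions are transformed back. Kernels: linear
($K = x^\top y$), RBF ($K = e^{-\gamma\|x-y\|^2}$), polynomial
($K = (\gamma x^\top y + 1)^d$, constant fixed at 1 to avoid the degenerate
homogeneous kernel).

### The genetic search

Each chromosome is one SVR configuration
$(\text{kernel}, C, \gamma, \varepsilon, d)$:

| gene | range | initialization | mutation |
|---|---|---|---|
| kernel | linear / rbf / poly | uniform | re-draw from the other two |
| $C$ | $[0.1, 1000]$ | log-uniform | Gaussian on log scale, sd = 10% of log-range, clipped |
| $\varepsilon$ | $[0.001, 1.0]$ | uniform | Gaussian, sd = 10% of range, clipped |
| $\gamma$ | $[10^{-5}, 10]$ | log-uniform | Gaussian on log scale, clipped |
| $d$ | $\{2,3,4,5\}$ | uniform | $\pm 1$, clipped |

Fitness is the 5-fold cross-validated mean squared error of SVR predictions
of the observed target values (lower is better); only the genes the selected
kernel uses enter the fit, and fitness values are cached by the
kernel-relevant genes. Selection is tournament of size 2; crossover (applied
to 80% of selected pairs) inherits the kernel gene uniformly and blends the
continuous genes as $\alpha g_1 + (1-\alpha) g_2$ with $\alpha \sim U(0,1)$
per gene event (the second offspring takes the complementary weight; the
integer degree is blended and rounded); each gene then mutates independently
with probability 0.1. One elite chromosome survives unchanged per
generation, which makes the best fitness trace non-increasing by
construction. The loop stops at the generation cap or after `patience`
generations without improvement beyond $10^{-6}$ — "run until the minimum is
reached" is not an operational stopping rule, so patience plus a hard cap
stands in.

Population size and generation count are not prescribed anywhere, so the
defaults (population 20, at most 15 generations, patience 5) are desk-scale
choices balanced against the $O(G \cdot P \cdot m^2)$ cost of the search.
Two further tractability decisions are worth knowing about:

* **Fitness subsampling.** Fitness evaluation caps the training rows at
  `fitness_rows` (default 400) using a seeded subsample; the *final*
  imputation fit always uses all observed rows. libsvm is quadratic-to-cubic
  in the row count, and hyperparameter *ranking* stabilizes long before the
  fit itself saturates.
* **Two solver tolerances.** Candidate configurations are ranked with the
  solver tolerance loosened to 0.01; the winning configuration is refitted
  and reported at the standard 0.001. Numerically extreme corners of the
  search space (polynomial kernels with $\gamma$ near 10, $C$ near 1000)
  otherwise dominate the runtime while never winning.

The search runs once per incomplete attribute (matching the per-target
structure of the imputation driver); a single shared search would be cheaper
but ties all attributes to one kernel.

### The imputation driver

`impute_dataset()` processes incomplete attributes in ascending order of
missing fraction (ties by column order): the most reliable targets are
completed first and immediately join the predictor pool of later, harder
targets. Categorical attributes are label-encoded (first-appearance order, a
deterministic rule), regressed on their integer codes, and predictions are
snapped to the nearest valid code, so imputed categorical cells always
decode to a real category. Remaining gaps in a *design matrix* (predictor
columns still incomplete at fit time) are mean-filled as temporary
scaffolding only — such fills are never written into the dataset. Observed
cells are never altered by any imputer, and the iterative strategy updates
only the originally missing cells.

Iterative SVR stops when the largest change of any imputed value (on the
standardized target scale) falls below `tol = 1e-3`, or after
`max_iter = 10` passes (flagged as non-converged). On convergence the
previous iterate is kept — the two differ by less than `tol` by definition,
and this makes the degenerate setting `tol = Inf` return exactly the
single-pass result. Whether the refit should also train on rows whose target
value was itself imputed is ambiguous; the default trains on originally
observed target rows only (with imputed predictor cells), and
`train_on_imputed = TRUE` switches to the alternative reading.

A per-attribute diagnostic reports the fraction of held-out CV predictions
whose standardized absolute residual is within `eps_acc` (default 0.05, the
midpoint of the plausible 0.001–0.1 band). It is a report, not a constraint:
nothing in the published procedure enforces it.

### The classifier

`induce_tree()` grows a binary CART tree with Gini-index splitting: node
impurity $GI = 1 - \sum_i p_i^2$, split quality = parent impurity minus the
child-size-weighted impurity, numeric thresholds at all midpoints of
adjacent distinct sorted values, nominal splits over all binary category
partitions (one-vs-rest beyond 10 categories, to bound the $2^{c-1}$
enumeration). Ties break deterministically toward the lower attribute index
and threshold. Numeric routing sends `value <= threshold` left; leaf ties
predict the lowest class in sort order. Growth stops only at purity or
degeneracy (min 2 rows to split, min 1 per leaf, unlimited depth):
complexity control is delegated entirely to minimal cost-complexity pruning
(`ccp_prune()`), which repeatedly collapses the internal node with the
smallest effective penalty $g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1)$
while $g(t) \le \alpha$. `alpha = 0` removes only zero-gain subtrees;
`alpha = Inf` leaves the majority-class stump. `export_rules()` prints one
rule per leaf with its class counts and Gini impurity.

## MAR injection and the synthetic generators

`inject_mar()` masks each target cell independently with probability
$\sigma(a + \beta^\top z_i)$, where $z_i$ are the standardized values of
fully observed *driver* attributes — missingness depends only on observed
values, the definition of missing-at-random. The intercept $a$ is calibrated
by bisection so the expected missing fraction matches the requested rate
(the realized fraction then lands within about $\pm 0.01$ at $n = 10{,}000$);
all-zero coefficients degrade gracefully to MCAR. Identical spec and seed
reproduce the identical mask.

The generators (`gen_numeric()`, `gen_mixed()`) produce tables with a known
ground truth for recovery scoring. No published generative law exists for
the reference synthetic benchmarks (only sizes, attribute kinds and rates:
5000×15 numeric at 27.6%, and 15000×30 mixed at 10%, available as
`spec_synthetic1()` / `spec_synthetic2()`), so the package commits to a
Gaussian latent-factor model: every attribute loads on one shared factor
(weight 0.4) plus one of three group factors (weight 0.8) with noise sd 0.4,
which guarantees the positive inter-attribute correlations the correlation
filter and the SVR stage are designed to exploit. The binary class
thresholds a linear score of the latent factors at zero, with 5% label
flips. Categorical attributes quantile-discretize latent scores into the
requested cardinalities.

**Who drives the mask matters.** The first numeric attribute is held out as
the MAR driver and never masked. Driving the mask from the class label
instead makes the missingness pattern itself class-informative — the subset
of fully complete rows becomes nearly single-class, row-deletion baselines
score absurdly well on it, and imputers' measured accuracy can *rise* with
the missing rate. Both effects were observed empirically and both invert the
comparisons the harness exists to make. The same holdout rule applies inside
`missingness_sweep()`.

What the generator does *not* emulate: heavy-tailed or multimodal marginals,
nonlinear dependencies between attributes, MNAR mechanisms, label noise
correlated with missingness, and the idiosyncrasies of real clinical
registries. Tests passing on these fixtures demonstrate the machinery's
correctness and the expected qualitative orderings, not performance on any
particular real dataset.

## The evaluation harness

`kfold_eval()` runs a stratified k-fold protocol with strict fold hygiene:
the imputer (including the genetic search) is fitted on training-fold rows
only; the tree is induced on the completed training fold; the test fold is
completed by the training-fitted imputer and scored. Each report carries an
audit trail of the row indices touched during fitting, and the test suite
asserts they never intersect the test fold. For the `drop` baseline,
deletion happens within each fold and test metrics are computed over the
surviving test rows. At apply time the per-attribute models fitted on the
training fold complete a new fold in a single pass (the KNN stage pools
training rows as donors); iterative refinement is a training-time device.
`compare_frameworks()` evaluates the nine frameworks (drop, mean, mode,
median, KNN, linear regression, neural network, canonical SVR with the fixed
default rbf/C=1/epsilon=0.1/gamma=1/p configuration, and the full adaptive
GA-optimized imputer) on identical folds; `missingness_sweep()` traces all
four metrics over missingness levels 10–50%. Binary tasks report
positive-class precision/recall/F (positive = second class in sort order
unless specified); more classes switch to macro averaging.

## Numerical choices and degenerate inputs

* Zero-variance columns get scale 1 during standardization and pass through
  as constants; a constant *response* short-circuits to a constant predictor
  (the epsilon tube would otherwise leave libsvm with an empty model).
* Categorical codes are assigned in first-appearance order — deterministic
  and seed-independent, so Pearson correlations downstream are reproducible.
  Codes are nominal; their ordering carries no meaning, and the SVR treats
  them as numeric scaffolding whose predictions are snapped back to codes.
* KNN distances are standardized Euclidean over the entries observed in both
  rows (mean over co-observed squared differences); rows sharing no observed
  attribute sit at infinite distance. Fewer than `k` donors: all donors are
  used, flagged. No donors: column mean/mode, flagged.
* `exp(log(x))` round-trips can land a hair outside a closed range; mutated
  genes are clamped back.
* All randomness flows through explicit integer seeds; derived child seeds
  stay below $2^{31}$. Package code saves and restores the caller's RNG
  state.

## Problem sizes used by the test suite

The acceptance-style tests run at deliberately desk-scale sizes, chosen once
as the package's own sizing: the split-search oracle on 50 random tables of
at most 8 rows; the genetic search against a deduplicated 900-point
exhaustive grid on a 70-row toy task (10 search seeds, shared CV folds);
ground-truth recovery on 1000 rows × 10 attributes at a 20% rate over 10
seeds with a lean search budget (population 4, 2 generations, fitness capped
at 60 rows); the deletion-vs-adaptive ordering on 600-row fixtures; the
degradation sweep endpoints (10% vs 50%) on 240-row fixtures over 3 seeds.
Where a lean budget replaces the package defaults, that is a statement about
the budget of the *test*, not about the method's defaults.

## Known limitations

* One imputation per cell — no multiple-imputation uncertainty propagation.
* The class attribute must be complete; imputing it is out of scope.
* The ρ ≤ 0 predictor filter discards anti-correlated (informative)
  predictors by design fidelity; the fallback only cushions the empty-set
  case.
* Label-encoded categoricals impose an arbitrary metric during regression;
  high-cardinality nominals are better served by the tree's subset splits
  than by the SVR stage.
* `drop` can empty a fold at high missingness with many attributes; the
  harness reports the error rather than papering over it.
* Runtime is dominated by libsvm on numerically extreme configurations;
  the subsampling and tolerance choices above are mitigations, not cures.
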