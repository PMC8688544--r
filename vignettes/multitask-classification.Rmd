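---
title: "Multi-task L2,1-regularized classification of expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task L2,1-regularized classification of expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmtl)
```

## The model and its assumptions

`panmtl` classifies samples into K classes from a normalized expression
matrix by treating each class as one binary *task*. All tasks share the
identical predictor matrix $X \in \mathbb{R}^{n \times p}$ (samples ×
genes, on a variance-stabilized continuous scale); task $i$'s response
$Y_i \in \{+1,-1\}^n$ marks membership of class $i$. The fit minimizes

$$
\min_{W, C} \; \sum_{i=1}^{t} \frac{1}{n}\sum_{k=1}^{n}
  \log\!\left(1 + e^{-Y_{i,k}(X_k W_i + C_i)}\right)
  \;+\; \lambda_1 \lVert W \rVert_{2,1}
  \;+\; \lambda_2 \lVert W \rVert_F^2 ,
$$

with $W \in \mathbb{R}^{p\times t}$ (one coefficient per gene per task)
and unpenalized intercepts $C \in \mathbb{R}^t$. The row-group norm
$\lVert W\rVert_{2,1} = \sum_j \lVert W_{j\cdot} \rVert_2$ couples the
tasks: a gene is kept or discarded for *all* classes jointly, which is
what makes the model a joint feature selector rather than K independent
lasso fits. The ridge term stabilizes correlated predictors. Because
every task shares $X$, each per-task loss is averaged over the full
sample count $n$; the per-task means are then summed over tasks. The
intercepts are left out of both penalties — the penalties are meant to
shrink gene effects, not the class prevalences the intercepts encode.

Prediction applies the task sigmoids column-wise:
$P_{ki} = \sigma(X_k W_i + C_i)$. These are independent one-vs-rest
probabilities and deliberately not normalized across tasks. A sample is
assigned the argmax class; ties break toward the lowest task index, and
a sample whose maximum probability is $\le 0.5$ keeps its argmax label
but carries a low-confidence flag — dropping such samples would corrupt
confusion-matrix accounting, so flagging is the only safe default.

## The solver

The objective is a smooth part (losses + ridge) plus the non-smooth
L2,1 term, the standard setting for accelerated proximal-gradient
(FISTA) methods, which is what `rmtl_fit()` implements:

* the smooth gradient is the analytic logistic-loss gradient per task
  column plus $2\lambda_2 W$;
* the L2,1 term enters only through its closed-form proximal operator,
  row-wise group soft-thresholding
  $r \mapsto \max(0, 1 - \tau/\lVert r\rVert_2)\, r$ (`prox_l21()`);
* a backtracking line search halves the step until the local quadratic
  majorization holds, so no Lipschitz constant is needed;
* a *monotone* acceptance rule keeps the previous iterate whenever the
  accelerated candidate would increase the objective, and restarts the
  momentum there. The recorded objective trace is therefore
  non-increasing by construction, which turns "the solver descended" into
  a checkable invariant rather than a hope.

Initialization is deterministic at $W = 0$, $C = 0$, where the objective
is exactly $t\ln 2$ — every fit is bit-reproducible and the first trace
value is analytically known. Iteration stops when the relative objective
change falls below `tolerance` (default $10^{-6}$) or after
`max_iterations` (default 5000). Two limits give useful sanity anchors:
at $t=1$ the problem is ordinary elastic-net-penalized logistic
regression (the test suite checks the fit against an independent
optimizer there), and for $\lambda_1$ larger than the largest initial
row-gradient norm the solution is intercept-only with
$C_i = \log(n_i^+/n_i^-)$, the log-odds of task prevalence.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda1` | `1e-4` | L2,1 strength; larger ⇒ fewer active gene rows |
| `lambda2` | `1e-5` | ridge strength; stabilizes correlated genes |
| `tolerance` | `1e-6` | relative objective-change stopping rule |
| `initial_step` | `1` | starting proximal step; backtracking adapts it |
| `backtracking_factor` | `0.5` | step multiplier on a failed line search |
| `test_fraction` | `0.2` | stratified 8:2 train/test split |
| `n_folds`, `n_repeats` | `10`, `10` | repeated stratified CV protocol |
| `bins` (mRMR) | `5` | equal-frequency discretization bins |
| `reg_c` (linear ranker) | `0.01` | inverse penalty of the OVR trainer |

The default penalties are the conventional best-performing point for
this model family on pan-cancer-scale data; `cv_grid_search()` exists
precisely so they are *selected*, not assumed, on new data. Its default
grid is logarithmic, $10^{-6}\dots10^{0}$ in both penalties, and
selection ties break toward the larger (sparser) penalties.

## Protocol choices

**Stratified split.** Within each class,
`max(1, floor(n_class * fraction + 0.5))` samples go to test. Half-up
rounding is deliberate (R's `round()` is half-to-even, which would starve
some odd-sized classes), and the minimum of one test sample keeps every
class evaluable. Per-class proportions in both partitions match the full
data within one sample.

**Cross-validation.** Each repeat draws a fresh stratified fold
assignment (per-class round-robin after a seeded shuffle, so every fold
contains every class whenever `k` ≤ the smallest class size); repeat
$r$ is seeded `seed + r - 1`. The selection score defaults to the
multiclass MCC — the metric of record for imbalanced multi-class
problems — with accuracy and log loss as alternatives. After selection
the model is refit on the entire training set and evaluated once on the
untouched test partition.

## Evaluation conventions

The confusion matrix is oriented rows = true, columns = predicted; the
multiclass MCC is computed from its marginals
($t_j$ = row sums, $p_j$ = column sums, $n_c$ = trace, $n_s$ = total) and
returns 0 when either factor under the square root vanishes (e.g. all
predictions in one class) — the statistic is undefined there and 0 is
the established convention. Log loss uses the natural logarithm; because
one-vs-rest sigmoids do not sum to one per sample, rows are renormalized
before evaluation and clipped to $[10^{-15}, 1-10^{-15}]$ so a confident
mistake costs a large finite amount rather than infinity. Per-class
precision for a never-predicted class is 0 with a warning. ROC curves
place thresholds at distinct scores (ties grouped), integrate AUC by the
trapezoid rule over the exact step curve, and PR curves start at
(recall 0, precision 1).

## Feature ranking

Two rankings are provided. The *coefficient* ranking trains one-vs-rest
linear max-margin classifiers (sample-averaged squared-hinge loss with an
L2 penalty weighted by `1/reg_c`, BFGS with analytic gradients — chosen
smooth so a generic quasi-Newton method solves it reliably; parity with
any particular SVM library is a non-goal, only the importance ordering
matters) and aggregates each gene's absolute coefficients across classes
by their maximum. Max-abs keeps genes that are decisive for even a single
class, which is the behavior wanted for heterogeneous multi-class panels;
sum-abs is available as an option. The *mRMR* ranking greedily maximizes
(relevance − mean redundancy) of mutual-information terms over
equal-frequency-binned expression, the MID criterion; binning ties
resolve by stable sample order so the discretization is identical across
platforms. All ranking ties break lexicographically by gene id. The
`subset_performance_curve()` helper re-runs the split/fit/evaluate loop
on nested top-$s$ subsets (the conventional ladder 75, 100, 200, …,
1000 by default) and reports test MCC per size.

## What the synthetic generator does and does not emulate

`simulate_expression()` draws i.i.d. Gaussian background expression
(`baseline_mean`, `noise_sd`) and shifts disjoint blocks of
`signal_genes_per_class` genes upward by `effect_size × noise_sd` in
their class's samples only. This mimics the *post-normalization* state
of a real pipeline — VST output with class-specific differentially
expressed genes against a common background — which is the input
contract of the classifier. The defaults (6 classes × 50 samples,
300 genes, 10 signal genes per class, effect size 2) are the package's
standard study conditions, sized so a full CV + fit + evaluate cycle
completes in seconds while leaving the recovery and accuracy checks
non-trivial.

It deliberately does **not** model: gene–gene correlation, batch
effects, count-level (negative-binomial) noise, or class-overlapping
signal: signal blocks are strictly disjoint, and sample-size imbalance
occurs only when requested through `samples_per_class`. Passing tests on this generator therefore
demonstrate correctness of the estimation and evaluation machinery, not
robustness to the full messiness of real RNA-seq cohorts.

## Known limitations

* Only the L2,1 cross-task regularizer is implemented; trace-norm,
  graph-Laplacian or clustered-task penalties are out of scope.
* No warm starts across the penalty grid; each grid point fits from the
  zero initialization (robust, but a solver-speed opportunity).
* Probability calibration across tasks is the simple row
  renormalization used for log loss; no Platt/isotonic recalibration.
* The solver is dense; at $p$ in the tens of thousands a screening rule
  or sparse-matrix path would be needed.
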