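# panmtl

Multi-class classification of gene-expression profiles by **regularized
multi-task learning** with joint feature selection, aimed at problems like
pan-cancer tumor typing: given a normalized (VST-scale) samples × genes
expression matrix and one class label per sample (e.g. 21 tumor types plus
a merged adjacent-normal class), learn all classes simultaneously and
report which genes drive the discrimination.

## The model

Each of the *t* classes becomes a one-vs-rest logistic task over the
*shared* predictor matrix *X* ∈ ℝ^{n×p}: task *i* has response
*Y_i* ∈ {+1, −1}^n, +1 for samples of class *i*. The model estimates a
coefficient matrix *W* ∈ ℝ^{p×t} (one column per task, one row per gene)
and intercepts *C* ∈ ℝ^t by minimizing the composite objective

```
min_{W,C}  Σ_{i=1..t} L(W_i, C_i | X, Y_i)  +  λ₁‖W‖₂,₁  +  λ₂‖W‖²_F
```

where `L` is the mean logistic loss
`(1/n) Σ_k log(1 + exp(−Y_{i,k}(X_k·W_i + C_i)))`,
`‖W‖₂,₁ = Σ_j ‖W_{j·}‖₂` is the row-group (L2,1) norm whose penalty zeroes
entire gene rows — removing a gene from **all** tasks at once — and the
squared Frobenius term is a ridge stabilizer. The objective is minimized
by an accelerated proximal-gradient (FISTA) solver with backtracking line
search and a monotone acceptance rule, using the closed-form row
soft-thresholding proximal operator for the L2,1 term. Unknown samples get
the class of their highest one-vs-rest probability (flagged low-confidence
when that maximum is ≤ 0.5).

Around the core model the package provides:

- **Evaluation for imbalanced multi-class data**: confusion matrix,
  accuracy, the multiclass Matthews correlation coefficient computed from
  the confusion-matrix marginals, natural-log cross-entropy (log loss),
  per-class precision/recall/F1 with macro and support-weighted
  aggregates, and one-vs-rest ROC / precision–recall curves with
  trapezoidal AUC.
- **Gene ranking**: by absolute coefficients of one-vs-rest linear
  max-margin classifiers, and by greedy mRMR (mutual-information
  difference criterion over equal-frequency bins); plus a test-MCC vs.
  subset-size curve for nested feature subsets.
- **Protocol utilities**: stratified 8:2 train/test splitting, repeated
  stratified k-fold cross-validation over a (λ₁, λ₂) grid, and an
  end-to-end `run_experiment()` that is byte-reproducible given a seed.
- **Synthetic data**: a seeded generator of VST-like expression matrices
  with planted class-specific signal-gene blocks, so the entire pipeline
  is verifiable without any external download.

## Worked example

```r
library(panmtl)

sim   <- simulate_expression(simulation_spec(seed = 11))   # 6 classes x 50, 300 genes
split <- stratified_split(sim$dataset, test_fraction = 0.2, seed = 42)
model <- rmtl_fit(build_tasks(split$train), lambda1 = 1e-4, lambda2 = 1e-5)
model
#> rmtl_model: 300 genes x 6 tasks, lambda1 = 0.0001, lambda2 = 1e-05
#>   117 active gene rows; 1010 iterations, converged: TRUE, final objective 0.00812139

report <- evaluate_predictions(split$test$labels, predict(model, split$test$X))
report
#> evaluation_report: 60 samples, 6 classes
#>   accuracy 1.0000 | MCC 1.0000 | log loss 0.0027
#>   macro    P 1.0000 R 1.0000 F1 1.0000
#>   weighted P 1.0000 R 1.0000 F1 1.0000
```

The fitted model keeps 117 of 300 gene rows active: the L2,1 penalty has
discarded most background genes while the 60 planted signal genes
dominate the largest row norms (58/60 = 97% land in the top 60). All 60
held-out samples are classified correctly, so accuracy and the multiclass
MCC are both 1, and the small log loss says the one-vs-rest probabilities
are confident as well as correct.

A command-line wrapper with `simulate`, `fit`, `cv`, `predict`,
`evaluate`, `rank-features` and `run` subcommands is installed at
`inst/cli/panmtl.R`:

```sh
Rscript inst/cli/panmtl.R simulate --out data --seed 1
Rscript inst/cli/panmtl.R run --expression data/expression.tsv \
    --labels data/labels.tsv --out results --folds 5 --repeats 1
```

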