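# Shared fixtures, computed lazily and cached for the whole test run.

# The standard synthetic fixture: 6 classes x 50 samples, 300 genes,
# 10 signal genes per class, effect size 2 (the generator defaults).
std_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_expression(simulation_spec(seed = 11))
    cache
  }
})

# One reference fit of the multi-task model on the full standard fixture at
# the conventional penalties; reused wherever a converged model is needed.
std_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tasks <- build_tasks(std_sim()$dataset)
      cache <<- rmtl_fit(tasks, 1e-4, 1e-5)
    }
    cache
  }
})

# A small dataset for fast pipeline-level tests.
small_sim <- function(seed = 5) {
  simulate_expression(simulation_spec(n_classes = 4, samples_per_class = 20,
                                      n_genes = 60,
                                      signal_genes_per_class = 5,
                                      effect_size = 2.5, seed = seed))
}

# Classical binary MCC from a 2x2 confusion matrix (rows = true,
# cols = predicted, class 1 = positive), the closed-form oracle.
binary_mcc_oracle <- function(cm) {
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

# Mann-Whitney AUC by exhaustive pair counting (ties count one half).
auc_pair_oracle <- function(pos, score) {
  ps <- score[pos]; ns <- score[!pos]
  total <- 0
  for (a in ps) for (b in ns)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(ps) * length(ns))
}
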