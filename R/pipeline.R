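#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds by per-class round-robin after a
#' seeded shuffle, so every fold contains every class whenever
#' `k <= smallest class size`.
#'
#' @param labels Character vector of class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > min(table(labels)))
    stop("n_folds exceeds the smallest class size (",
         min(table(labels)), ")", call. = FALSE)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validation specification
#'
#' Defaults follow the standard protocol for this model family: 10-fold
#' cross-validation repeated 10 times, selecting penalties by multiclass
#' MCC (the headline metric for imbalanced multi-class data). The default
#' grid is logarithmic over 10^-6 .. 10^0 in both penalties.
#'
#' @param lambda1_grid,lambda2_grid Nonnegative penalty grids.
#' @param n_folds Folds per repeat (>= 2), default 10.
#' @param n_repeats Number of repeats, default 10.
#' @param seed Integer seed; repeat r uses `seed + r - 1` for its fold
#'   assignment.
#' @param scoring `"mcc"`, `"accuracy"` (maximized) or `"log_loss"`
#'   (minimized).
#' @return A list of class `cv_spec`.
#' @export
cv_spec <- function(lambda1_grid = 10^seq(-6, 0), lambda2_grid = 10^seq(-6, 0),
                    n_folds = 10L, n_repeats = 10L, seed = 1L,
                    scoring = c("mcc", "accuracy", "log_loss")) {
  scoring <- match.arg(scoring)
  if (length(lambda1_grid) == 0 || length(lambda2_grid) == 0)
    stop("penalty grids must be non-empty", call. = FALSE)
  if (any(lambda1_grid < 0) || any(lambda2_grid < 0))
    stop("penalties must be nonnegative", call. = FALSE)
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(lambda1_grid = lambda1_grid, lambda2_grid = lambda2_grid,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 scoring = scoring),
            class = "cv_spec")
}

# Score one fold's held-out predictions under the requested criterion.
#' @noRd
cv_score <- function(truth, proba, class_names, scoring) {
  switch(scoring,
         mcc = {
           pred <- predict_labels(proba, class_names)
           multiclass_mcc(confusion_matrix(truth, pred$label,
                                           sort(unique(c(truth, class_names)))))
         },
         accuracy = {
           pred <- predict_labels(proba, class_names)
           mean(pred$label == truth)
         },
         log_loss = log_loss(truth, proba, class_names))
}

#' Repeated stratified cross-validated penalty search
#'
#' For each repeat, a fresh seeded stratified fold assignment; for each
#' grid point, the model is fit on k-1 folds and scored on the held-out
#' fold; scores are averaged over all folds x repeats. The best point
#' maximizes the mean score (minimizes, for log loss); ties break toward
#' larger `lambda1`, then larger `lambda2` (preferring the sparser model).
#'
#' @param train An [expression_dataset()] (training portion only).
#' @param spec A [cv_spec()].
#' @param control [rmtl_control()] passed to each fit.
#' @return Object of class `cv_result`: `best_lambda1`, `best_lambda2`,
#'   and `table` (data frame: lambda1, lambda2, mean_score, sd_score).
#' @export
cv_grid_search <- function(train, spec, control = rmtl_control()) {
  stopifnot(inherits(train, "expression_dataset"), inherits(spec, "cv_spec"))
  grid <- expand.grid(lambda1 = spec$lambda1_grid,
                      lambda2 = spec$lambda2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  class_names <- sort(unique(train$labels))
  scores <- matrix(NA_real_, nrow(grid), spec$n_folds * spec$n_repeats)
  col <- 0L
  for (r in seq_len(spec$n_repeats)) {
    folds <- stratified_folds(train$labels, spec$n_folds, spec$seed + r - 1L)
    for (f in seq_len(spec$n_folds)) {
      col <- col + 1L
      tr <- subset_dataset(train, samples = which(folds != f))
      te <- subset_dataset(train, samples = which(folds == f))
      tasks <- build_tasks(tr, class_order = class_names)
      for (g in seq_len(nrow(grid))) {
        model <- rmtl_fit(tasks, grid$lambda1[g], grid$lambda2[g], control)
        proba <- predict(model, te$X)
        scores[g, col] <- cv_score(te$labels, proba, class_names,
                                   spec$scoring)
      }
    }
  }
  tab <- data.frame(lambda1 = grid$lambda1, lambda2 = grid$lambda2,
                    mean_score = rowMeans(scores),
                    sd_score = apply(scores, 1, stats::sd))
  key <- if (spec$scoring == "log_loss") -tab$mean_score else tab$mean_score
  ord <- order(-key, -tab$lambda1, -tab$lambda2)
  best <- ord[1]
  structure(list(best_lambda1 = tab$lambda1[best],
                 best_lambda2 = tab$lambda2[best],
                 scoring = spec$scoring, table = tab),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): best lambda1 = %g, lambda2 = %g\n",
              x$scoring, x$best_lambda1, x$best_lambda2))
  invisible(x)
}

#' Build an experiment configuration
#'
#' @param dataset An in-memory [expression_dataset()]; alternatively give
#'   `expression_file` + `labels_file`.
#' @param expression_file,labels_file TSV input paths (ignored when
#'   `dataset` is supplied).
#' @param test_fraction Held-out fraction, default 0.2 (8:2 split).
#' @param split_seed Seed of the stratified split.
#' @param cv A [cv_spec()], or NULL to skip the search and use `lambda1`,
#'   `lambda2` directly.
#' @param lambda1,lambda2 Penalties used when `cv` is NULL (defaults
#'   1e-4 and 1e-5, the conventional best point for this model family).
#' @param ranking Optional [read_feature_ranking()] result or TSV path;
#'   with `top_genes`, the dataset is restricted to the top-ranked genes
#'   before splitting.
#' @param top_genes Optional subset size applied to `ranking`.
#' @param control [rmtl_control()] for all fits.
#' @param output_dir Directory for artifacts, or NULL to write nothing.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(dataset = NULL, expression_file = NULL,
                              labels_file = NULL, test_fraction = 0.2,
                              split_seed = 1L, cv = NULL,
                              lambda1 = 1e-4, lambda2 = 1e-5,
                              ranking = NULL, top_genes = NULL,
                              control = rmtl_control(), output_dir = NULL) {
  if (is.null(dataset) && (is.null(expression_file) || is.null(labels_file)))
    stop("either dataset or expression_file + labels_file required",
         call. = FALSE)
  structure(list(dataset = dataset, expression_file = expression_file,
                 labels_file = labels_file, test_fraction = test_fraction,
                 split_seed = as.integer(split_seed), cv = cv,
                 lambda1 = lambda1, lambda2 = lambda2, ranking = ranking,
                 top_genes = top_genes, control = control,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Keys mirror the arguments of [experiment_config()]; `cv` may be a
#' nested map with `cv_spec()` keys.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cv <- if (!is.null(cfg$cv)) do.call(cv_spec, cfg$cv) else NULL
  control <- if (!is.null(cfg$control)) do.call(rmtl_control, cfg$control)
             else rmtl_control()
  experiment_config(expression_file = cfg$expression_file,
                    labels_file = cfg$labels_file,
                    test_fraction = cfg$test_fraction %||% 0.2,
                    split_seed = cfg$split_seed %||% 1L,
                    cv = cv,
                    lambda1 = cfg$lambda1 %||% 1e-4,
                    lambda2 = cfg$lambda2 %||% 1e-5,
                    ranking = cfg$ranking,
                    top_genes = cfg$top_genes,
                    control = control,
                    output_dir = cfg$output_dir)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an end-to-end train/evaluate experiment
#'
#' Executes: read (or take) the dataset -> optionally restrict to the
#' top-ranked genes -> stratified split -> cross-validated penalty search
#' on the training portion (when a `cv` spec is given) -> refit on the
#' whole training set at the selected penalties -> evaluate on the
#' untouched test set. With an `output_dir`, writes the model bundle, the
#' report JSON, confusion and curve TSVs, the split manifest and a run
#' log recording every seed and setting. Identical configurations produce
#' byte-identical reports.
#'
#' @param config An [experiment_config()].
#' @return List of class `experiment_result`: `report`
#'   (an [evaluate_predictions()] result), `model`, `cv` (NULL without a
#'   search), `split`, and `settings` (the seeds and penalties used).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  data <- config$dataset
  if (is.null(data)) {
    for (f in c(config$expression_file, config$labels_file))
      if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
    data <- read_dataset(config$expression_file, config$labels_file)
  }
  if (!is.null(config$ranking)) {
    ranking <- if (inherits(config$ranking, "feature_ranking")) config$ranking
               else read_feature_ranking(config$ranking)
    s <- config$top_genes %||% length(ranking$genes)
    data <- subset_dataset(data, genes = ranking$genes[seq_len(s)])
  }
  split <- stratified_split(data, config$test_fraction, config$split_seed)
  cv_res <- NULL
  lambda1 <- config$lambda1; lambda2 <- config$lambda2
  if (!is.null(config$cv)) {
    cv_res <- cv_grid_search(split$train, config$cv, config$control)
    lambda1 <- cv_res$best_lambda1; lambda2 <- cv_res$best_lambda2
  }
  tasks <- build_tasks(split$train)
  model <- rmtl_fit(tasks, lambda1, lambda2, config$control)
  proba <- predict(model, split$test$X)
  report <- evaluate_predictions(split$test$labels, proba)
  settings <- list(split_seed = config$split_seed,
                   test_fraction = config$test_fraction,
                   cv_seed = if (!is.null(config$cv)) config$cv$seed,
                   n_folds = if (!is.null(config$cv)) config$cv$n_folds,
                   n_repeats = if (!is.null(config$cv)) config$cv$n_repeats,
                   scoring = if (!is.null(config$cv)) config$cv$scoring,
                   lambda1 = lambda1, lambda2 = lambda2,
                   top_genes = config$top_genes,
                   tolerance = config$control$tolerance,
                   max_iterations = config$control$max_iterations)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$output_dir, f)
    write_rmtl_model(model, out("model"))
    write_evaluation_report(report, out("report.json"))
    write_confusion_tsv(report$confusion, out("confusion.tsv"))
    write_curves_tsv(report$curves, out("curves.tsv"))
    write_split_manifest(split, out("split.tsv"))
    jsonlite::write_json(settings, out("run_log.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  structure(list(report = report, model = model, cv = cv_res, split = split,
                 settings = settings),
            class = "experiment_result")
}
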