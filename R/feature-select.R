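#' Train one-vs-rest linear max-margin classifiers
#'
#' Fits, for each class, a linear classifier minimizing the sample-averaged
#' squared-hinge loss plus an L2 penalty weighted by `1 / reg_c`
#' (intercept unpenalized), via BFGS with analytic gradients. Its purpose
#' here is coefficient extraction for gene ranking, not benchmark parity
#' with any particular SVM solver: only the resulting importance ordering
#' is contractual.
#'
#' @param data An [expression_dataset()] with at least 2 classes.
#' @param reg_c Positive regularization parameter (inverse penalty
#'   weight); default 0.01.
#' @return List with `coef` (genes x classes matrix), `intercepts`
#'   (length-K vector) and `class_names`.
#' @export
train_linear_ovr <- function(data, reg_c = 0.01) {
  stopifnot(inherits(data, "expression_dataset"))
  if (reg_c <= 0) stop("reg_c must be positive", call. = FALSE)
  classes <- sort(unique(data$labels))
  if (length(classes) < 2)
    stop("at least 2 classes required", call. = FALSE)
  X <- data$X; n <- nrow(X); p <- ncol(X)
  lam <- 1 / (2 * reg_c)
  fit_one <- function(y) {
    fn <- function(par) {
      w <- par[1:p]; b <- par[p + 1]
      s <- pmax(0, 1 - y * (drop(X %*% w) + b))
      mean(s^2) + lam * sum(w^2)
    }
    gr <- function(par) {
      w <- par[1:p]; b <- par[p + 1]
      s <- pmax(0, 1 - y * (drop(X %*% w) + b))
      g <- -2 * s * y / n
      c(drop(crossprod(X, g)) + 2 * lam * w, sum(g))
    }
    res <- stats::optim(rep(0, p + 1), fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    res$par
  }
  coef <- matrix(0, p, length(classes),
                 dimnames = list(data$gene_ids, classes))
  intercepts <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_along(classes)) {
    y <- ifelse(data$labels == classes[i], 1, -1)
    par <- fit_one(y)
    coef[, i] <- par[1:p]
    intercepts[i] <- par[p + 1]
  }
  list(coef = coef, intercepts = intercepts, class_names = classes)
}

#' Rank genes by linear-classifier coefficient magnitude
#'
#' Aggregates each gene's absolute coefficients across the K one-vs-rest
#' columns -- by default taking the maximum, which preserves genes that are
#' decisive for even a single class (`"sum"` is available as an
#' alternative) -- and sorts genes by descending score. Ties break by
#' lexicographic gene id.
#'
#' @param coef Numeric p-by-K coefficient matrix.
#' @param gene_ids Gene identifier per row of `coef` (defaults to its row
#'   names).
#' @param aggregate `"max"` (default) or `"sum"` of absolute coefficients
#'   across classes.
#' @return Object of class `feature_ranking`: list with `method`
#'   (`"coefficient"`), `genes` (most important first), `scores`
#'   (non-increasing) and `params`.
#' @export
rank_by_coefficients <- function(coef, gene_ids = rownames(coef),
                                 aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  coef <- as.matrix(coef)
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(coef)))
  if (length(gene_ids) != nrow(coef))
    stop_dims("gene_ids", nrow(coef), length(gene_ids))
  score <- if (aggregate == "max") apply(abs(coef), 1, max)
           else rowSums(abs(coef))
  ord <- order(-score, gene_ids)
  structure(list(method = "coefficient",
                 genes = as.character(gene_ids)[ord],
                 scores = unname(score[ord]),
                 params = list(aggregate = aggregate)),
            class = "feature_ranking")
}

# Equal-frequency discretization; ties broken by stable sample order so the
# binning is identical across runs and platforms.
#' @noRd
discretize_ef <- function(x, bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

# Mutual information (nats) between two discrete vectors, from the
# contingency table.
#' @noRd
mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  nz <- pij > 0
  sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
}

#' Minimum-redundancy-maximum-relevance (mRMR) gene ranking
#'
#' Greedy forward selection under the MID (mutual-information difference)
#' criterion: each expression column is discretized into `bins`
#' equal-frequency bins; relevance is the mutual information between a
#' gene and the class label, redundancy the mean mutual information with
#' already-selected genes; each step picks the gene maximizing
#' relevance - redundancy (first pick: maximal relevance). Ties break by
#' lexicographic gene id. Constant columns get zero relevance.
#'
#' @param data An [expression_dataset()].
#' @param k Number of genes to select (<= number of genes).
#' @param bins Number of equal-frequency bins (default 5).
#' @return Object of class `feature_ranking` with `method = "mrmr"`;
#'   `scores` are the MID values at selection time.
#' @export
mrmr_rank <- function(data, k, bins = 5L) {
  stopifnot(inherits(data, "expression_dataset"))
  p <- ncol(data$X)
  if (k > p) stop("k exceeds the number of genes (", p, ")", call. = FALSE)
  if (k < 1) stop("k must be positive", call. = FALSE)
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  D <- apply(data$X, 2, discretize_ef, bins = bins)
  y <- data$labels
  relevance <- apply(D, 2, mutual_information, b = y)
  selected <- integer(0)
  scores <- numeric(0)
  # cumulative MI of every candidate with the selected set
  red_sum <- numeric(p)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    crit <- if (length(selected) == 0) relevance[remaining]
            else relevance[remaining] - red_sum[remaining] / length(selected)
    ord <- order(-crit, data$gene_ids[remaining])
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    scores <- c(scores, crit[ord[1]])
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0 && step < k) {
      red_sum[remaining] <- red_sum[remaining] +
        apply(D[, remaining, drop = FALSE], 2, mutual_information,
              b = D[, pick])
    }
  }
  structure(list(method = "mrmr",
                 genes = data$gene_ids[selected],
                 scores = unname(scores),
                 params = list(k = as.integer(k), bins = as.integer(bins),
                               criterion = "MID")),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking (%s): %d genes\n", x$method, length(x$genes)))
  n <- min(5, length(x$genes))
  cat("  top:", paste(sprintf("%s (%.4g)", x$genes[1:n], x$scores[1:n]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Test-set MCC as a function of feature-subset size
#'
#' For each requested size s: restricts the dataset to the top-s ranked
#' genes, makes a stratified train/test split, fits a model on train and
#' evaluates the multiclass MCC on test. The default model factory fits
#' the multi-task L2,1 model at the given penalties.
#'
#' @param data An [expression_dataset()].
#' @param ranking A [rank_by_coefficients()] / [mrmr_rank()] result (or any
#'   `feature_ranking`); every size must not exceed its length.
#' @param sizes Integer vector of subset sizes; default the conventional
#'   ladder 75, 100, 200, ..., 1000 (truncated to the ranking length).
#' @param split_seed Seed for the stratified split.
#' @param test_fraction Test fraction, default 0.2.
#' @param fit_fun Model factory: function(train_dataset) returning an
#'   object usable with `predict(., X)`. Defaults to
#'   `rmtl_fit` at `lambda1`, `lambda2`.
#' @param lambda1,lambda2 Penalties for the default factory.
#' @param control [rmtl_control()] for the default factory.
#' @return Data frame with columns `size` and `mcc`.
#' @export
subset_performance_curve <- function(data, ranking,
                                     sizes = c(75, 100, 200, 300, 400, 500,
                                               600, 700, 800, 900, 1000),
                                     split_seed, test_fraction = 0.2,
                                     fit_fun = NULL,
                                     lambda1 = 1e-4, lambda2 = 1e-5,
                                     control = rmtl_control()) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(ranking, "feature_ranking"))
  if (any(sizes > length(ranking$genes)))
    stop("size exceeds ranking length (", length(ranking$genes), ")",
         call. = FALSE)
  if (is.null(fit_fun)) {
    fit_fun <- function(train) {
      rmtl_fit(build_tasks(train), lambda1, lambda2, control)
    }
  }
  mccs <- vapply(sizes, function(s) {
    sub <- subset_dataset(data, genes = ranking$genes[seq_len(s)])
    split <- stratified_split(sub, test_fraction, split_seed)
    model <- fit_fun(split$train)
    proba <- predict(model, split$test$X)
    pred <- predict_labels(proba)
    cm <- confusion_matrix(split$test$labels, pred$label,
                           sort(unique(data$labels)))
    multiclass_mcc(cm)
  }, numeric(1))
  data.frame(size = as.integer(sizes), mcc = mccs)
}

#' Write a feature ranking as TSV plus a JSON params sidecar
#'
#' @param ranking A `feature_ranking`.
#' @param path Output TSV path (gene id, score); params are written to
#'   `<path>.params.json`.
#' @return Invisibly, the TSV path.
#' @export
write_feature_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "feature_ranking"))
  utils::write.table(data.frame(gene_id = ranking$genes,
                                score = format_full(ranking$scores)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(method = ranking$method), ranking$params),
                       paste0(path, ".params.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a feature ranking written by [write_feature_ranking()]
#'
#' @param path The TSV path.
#' @return A `feature_ranking`.
#' @export
read_feature_ranking <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  params_path <- paste0(path, ".params.json")
  params <- if (file.exists(params_path))
    jsonlite::read_json(params_path, simplifyVector = TRUE) else list()
  method <- if (!is.null(params$method)) params$method else "coefficient"
  params$method <- NULL
  structure(list(method = method, genes = df$gene_id,
                 scores = as.numeric(df$score), params = params),
            class = "feature_ranking")
}
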