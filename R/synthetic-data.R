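#' Specification of a synthetic expression dataset
#'
#' Describes a VST-scale multi-class expression matrix with planted
#' class-specific signal genes: disjoint blocks of
#' `signal_genes_per_class` genes are shifted upward by
#' `effect_size * noise_sd` in their class's samples only, against an
#' i.i.d. Gaussian background. This emulates the post-normalization
#' differential-expression structure the classifier consumes; it makes no
#' attempt at count-level realism or gene-gene correlation.
#'
#' Defaults describe the package's standard study conditions: 6 classes of
#' 50 samples, 300 genes, 10 signal genes per class, a 2-SD mean shift.
#'
#' @param n_classes Number of classes (>= 2).
#' @param samples_per_class Integer vector of per-class sample counts
#'   (recycled to `n_classes`; imbalance allowed).
#' @param n_genes Total number of genes.
#' @param signal_genes_per_class Signal genes planted per class; blocks are
#'   disjoint so `n_classes * signal_genes_per_class <= n_genes`.
#' @param effect_size Mean shift of signal genes in noise-SD units.
#' @param noise_sd Standard deviation of the Gaussian background.
#' @param baseline_mean Background mean expression.
#' @param seed Integer seed; the same spec is bit-reproducible.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_classes = 6L, samples_per_class = 50L,
                            n_genes = 300L, signal_genes_per_class = 10L,
                            effect_size = 2, noise_sd = 1, baseline_mean = 0,
                            seed = 1L) {
  n_classes <- as.integer(n_classes)
  samples_per_class <- rep_len(as.integer(samples_per_class), n_classes)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (any(samples_per_class < 1))
    stop("samples_per_class must be positive", call. = FALSE)
  if (n_genes < 1) stop("n_genes must be positive", call. = FALSE)
  if (signal_genes_per_class < 1)
    stop("signal_genes_per_class must be positive", call. = FALSE)
  if (n_classes * signal_genes_per_class > n_genes)
    stop("signal blocks are disjoint: n_classes * signal_genes_per_class ",
         "must not exceed n_genes", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be nonnegative", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(list(n_classes = n_classes, samples_per_class = samples_per_class,
                 n_genes = as.integer(n_genes),
                 signal_genes_per_class = as.integer(signal_genes_per_class),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a labeled expression dataset with known signal genes
#'
#' Draws background expression i.i.d. Normal(baseline_mean, noise_sd) and
#' adds `effect_size * noise_sd` to class k's signal-gene block in class-k
#' samples only. Deterministic given the spec's seed. Gene ids are
#' "G0001...", sample ids "S0001...", class names "C01...".
#'
#' @param spec A [simulation_spec()].
#' @return Object of class `simulated_dataset`: list with `dataset` (an
#'   [expression_dataset()]), `truth` (named list: class -> its signal gene
#'   ids) and `spec`.
#' @examples
#' sim <- simulate_expression(simulation_spec(seed = 7))
#' sim$dataset
#' sim$truth$C01
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- sum(spec$samples_per_class)
  p <- spec$n_genes
  classes <- sprintf("C%02d", seq_len(spec$n_classes))
  labels <- rep(classes, spec$samples_per_class)
  gene_ids <- sprintf("G%04d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))
  X <- with_seed(spec$seed,
                 matrix(stats::rnorm(n * p, spec$baseline_mean, spec$noise_sd),
                        n, p))
  truth <- list()
  shift <- spec$effect_size * spec$noise_sd
  for (k in seq_len(spec$n_classes)) {
    block <- (k - 1) * spec$signal_genes_per_class +
      seq_len(spec$signal_genes_per_class)
    rows <- which(labels == classes[k])
    X[rows, block] <- X[rows, block] + shift
    truth[[classes[k]]] <- gene_ids[block]
  }
  structure(list(dataset = expression_dataset(X, labels = labels,
                                              sample_ids = sample_ids,
                                              gene_ids = gene_ids),
                 truth = truth, spec = spec),
            class = "simulated_dataset")
}

#' Write the ground-truth signal-gene map as JSON
#'
#' @param sim A [simulate_expression()] result.
#' @param path Output JSON path (class -> signal gene ids).
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_dataset"))
  jsonlite::write_json(sim$truth, path, pretty = TRUE)
  invisible(path)
}
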