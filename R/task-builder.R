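#' Construct a labeled expression dataset
#'
#' Bundles a samples-by-genes matrix of normalized (VST-like, continuous)
#' expression values with sample identifiers, gene identifiers and one class
#' label per sample. This is the common input container for task
#' construction, feature ranking and the end-to-end pipeline.
#'
#' @param X Numeric matrix, samples in rows, genes in columns. All values
#'   must be finite.
#' @param labels Character vector of class labels, one per row of `X`.
#' @param sample_ids Unique sample identifiers; defaults to `rownames(X)`.
#' @param gene_ids Unique gene identifiers; defaults to `colnames(X)`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `X`, `sample_ids`, `gene_ids`, `labels`.
#' @examples
#' X <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("S", 1:4), paste0("G", 1:5)))
#' ds <- expression_dataset(X, labels = c("A", "A", "B", "B"))
#' ds
#' @export
expression_dataset <- function(X, labels, sample_ids = rownames(X),
                               gene_ids = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(X)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  labels <- as.character(labels)
  if (length(sample_ids) != nrow(X))
    stop_dims("sample_ids", nrow(X), length(sample_ids))
  if (length(gene_ids) != ncol(X))
    stop_dims("gene_ids", ncol(X), length(gene_ids))
  if (length(labels) != nrow(X))
    stop_dims("labels", nrow(X), length(labels))
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("gene_ids must be unique", call. = FALSE)
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at sample '%s', gene '%s'",
                 sample_ids[bad[1]], gene_ids[bad[2]]), call. = FALSE)
  }
  dimnames(X) <- list(sample_ids, gene_ids)
  structure(list(X = X, sample_ids = sample_ids, gene_ids = gene_ids,
                 labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d genes, %d classes\n",
              nrow(x$X), ncol(x$X), length(unique(x$labels))))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset an expression dataset
#'
#' @param data An [expression_dataset()].
#' @param samples Optional index/logical/character vector of samples to keep.
#' @param genes Optional index/logical/character vector of genes to keep.
#' @return A new `expression_dataset`.
#' @export
subset_dataset <- function(data, samples = NULL, genes = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(data$X)) else samples
  gi <- if (is.null(genes)) seq_len(ncol(data$X)) else genes
  if (is.character(si)) si <- match(si, data$sample_ids)
  if (is.character(gi)) gi <- match(gi, data$gene_ids)
  if (anyNA(si)) stop("unknown sample id in subset", call. = FALSE)
  if (anyNA(gi)) stop("unknown gene id in subset", call. = FALSE)
  expression_dataset(data$X[si, gi, drop = FALSE],
                     labels = data$labels[si],
                     sample_ids = data$sample_ids[si],
                     gene_ids = data$gene_ids[gi])
}

#' Construct a multi-task set directly
#'
#' Low-level constructor pairing a shared predictor matrix with one +/-1
#' response column per task. Most users should call [build_tasks()] on a
#' labeled dataset instead; this constructor exists for hand-built task
#' structures (e.g. a single binary task).
#'
#' @param X Numeric n-by-p predictor matrix shared by all tasks.
#' @param Y Numeric n-by-t matrix with entries in {+1, -1}.
#' @param task_names Character vector of t task (class) names.
#' @param gene_ids,sample_ids Identifiers; generated if missing.
#' @return An object of class `task_set`.
#' @export
task_set <- function(X, Y, task_names, gene_ids = colnames(X),
                     sample_ids = rownames(X)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) stop_dims("Y rows", nrow(X), nrow(Y))
  if (length(task_names) != ncol(Y)) stop_dims("task_names", ncol(Y), length(task_names))
  if (anyDuplicated(task_names)) stop("task_names must be unique", call. = FALSE)
  check_pm1(Y, "task responses")
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(X)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  colnames(Y) <- task_names
  structure(list(X = X, Y = Y, task_names = as.character(task_names),
                 gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "task_set")
}

#' Build one-vs-rest tasks from a labeled dataset
#'
#' Every class becomes one binary task over the shared predictor matrix:
#' the response column for class k is +1 for samples of class k and -1 for
#' all other samples. All tasks therefore share the identical predictor
#' matrix and differ only in their responses.
#'
#' @param data An [expression_dataset()].
#' @param class_order Optional permutation of the distinct labels fixing the
#'   task order; defaults to lexicographically sorted labels.
#' @return A [task_set()] with one column of `Y` per class.
#' @examples
#' ds <- expression_dataset(matrix(rnorm(12), 4, 3),
#'                          labels = c("A", "A", "B", "C"))
#' ts <- build_tasks(ds)
#' ts$Y
#' @export
build_tasks <- function(data, class_order = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  classes <- sort(unique(data$labels))
  if (!is.null(class_order)) {
    if (!setequal(class_order, classes) || length(class_order) != length(classes))
      stop("class_order must be a permutation of the observed labels; unseen: ",
           paste(setdiff(class_order, classes), collapse = ", "), call. = FALSE)
    classes <- as.character(class_order)
  }
  Y <- vapply(classes, function(cl) ifelse(data$labels == cl, 1, -1),
              numeric(length(data$labels)))
  Y <- matrix(Y, nrow = length(data$labels), ncol = length(classes))
  task_set(data$X, Y, task_names = classes, gene_ids = data$gene_ids,
           sample_ids = data$sample_ids)
}

#' Recover labels from a task set
#'
#' Inverse of [build_tasks()]: reads each sample's class off the unique +1
#' entry in its response row.
#'
#' @param tasks A [task_set()] built from labeled data.
#' @return Character vector of class labels.
#' @export
tasks_to_labels <- function(tasks) {
  stopifnot(inherits(tasks, "task_set"))
  pos <- apply(tasks$Y == 1, 1, which)
  if (is.list(pos) || !all(rowSums(tasks$Y == 1) == 1))
    stop("task set is not one-vs-rest: a row lacks a unique +1", call. = FALSE)
  tasks$task_names[unlist(pos)]
}

#' Stratified train/test split
#'
#' Splits a dataset class by class so that per-class proportions in train
#' and test match the full dataset to within one sample. Within each class,
#' `max(1, round_half_up(n_class * test_fraction))` samples are drawn into
#' the test partition by the seeded generator; the remainder stay in train.
#'
#' @param data An [expression_dataset()].
#' @param test_fraction Fraction of each class assigned to test, in (0, 1).
#'   Default 0.2 (an 8:2 split).
#' @param seed Integer seed making the split reproducible.
#' @return An object of class `split_result`: list with `train` and `test`
#'   datasets plus the `seed` and `ratio` used.
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  tab <- table(data$labels)
  if (any(tab < 2))
    stop("class '", names(tab)[which(tab < 2)[1]],
         "' has fewer than 2 samples and cannot be split", call. = FALSE)
  test_idx <- with_seed(seed, {
    unlist(lapply(sort(unique(data$labels)), function(cl) {
      idx <- which(data$labels == cl)
      n_test <- max(1L, round_half_up(length(idx) * test_fraction))
      if (n_test >= length(idx)) n_test <- length(idx) - 1L
      sort(sample(idx, n_test))
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(data$labels), test_idx)
  structure(list(train = subset_dataset(data, samples = train_idx),
                 test = subset_dataset(data, samples = test_idx),
                 seed = as.integer(seed), ratio = test_fraction),
            class = "split_result")
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of gene identifiers and a first column of sample
#' identifiers; remaining cells are tab-separated numeric expression values.
#'
#' @param path Path to the tab-separated file.
#' @return A numeric matrix with sample row names and gene column names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

#' Read a sample-label table from TSV
#'
#' Two columns: sample identifier and class name (header row required).
#'
#' @param path Path to the tab-separated file.
#' @return Named character vector of class labels keyed by sample id.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Load a labeled dataset from expression + label TSV files
#'
#' Sample order is taken from the expression file; labels are joined by
#' sample id and any expression sample without a label is an error.
#'
#' @param expression_path Expression TSV (see [read_expression_tsv()]).
#' @param labels_path Label TSV (see [read_labels_tsv()]).
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(expression_path, labels_path) {
  X <- read_expression_tsv(expression_path)
  lab <- read_labels_tsv(labels_path)
  missing <- setdiff(rownames(X), names(lab))
  if (length(missing) > 0)
    stop("samples without labels: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  expression_dataset(X, labels = unname(lab[rownames(X)]))
}

#' Write an expression dataset to TSV files
#'
#' @param data An [expression_dataset()].
#' @param expression_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(data, expression_path, labels_path) {
  stopifnot(inherits(data, "expression_dataset"))
  df <- data.frame(sample_id = data$sample_ids,
                   data$X, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = data$sample_ids,
                                class = data$labels),
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression_path, labels_path))
}

#' Write a split manifest
#'
#' Records which partition each sample fell into as a two-column TSV
#' (sample id, partition).
#'
#' @param split A [stratified_split()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  df <- rbind(data.frame(sample_id = split$train$sample_ids, partition = "train"),
              data.frame(sample_id = split$test$sample_ids, partition = "test"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
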