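#' Mean logistic loss of a single binary task
#'
#' Computes `(1/n) * sum_k log(1 + exp(-y_k * (x_k . w + c)))` with labels
#' in {+1, -1} and the natural logarithm. Evaluated through a softplus form
#' that never exponentiates a large positive argument, so it is stable for
#' margins of any magnitude.
#'
#' @param X Numeric n-by-p predictor matrix.
#' @param y Response vector of +1/-1, length n.
#' @param w Coefficient vector, length p.
#' @param c Scalar intercept.
#' @return Nonnegative scalar, the mean logistic loss.
#' @examples
#' X <- matrix(rnorm(15), 5, 3)
#' logistic_loss(X, rep(c(1, -1), length.out = 5), rep(0, 3), 0)  # log(2)
#' @export
logistic_loss <- function(X, y, w, c) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop_dims("y", nrow(X), length(y))
  if (length(w) != ncol(X)) stop_dims("w", ncol(X), length(w))
  check_pm1(y)
  m <- y * (drop(X %*% w) + c)
  mean(softplus(-m))
}

# softplus(z) = log(1 + exp(z)), computed as max(z, 0) + log1p(exp(-|z|)).
#' @noRd
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

#' L2,1 norm of a coefficient matrix
#'
#' Sum over rows (genes) of each row's Euclidean norm across columns
#' (tasks). Penalizing this norm zeroes entire rows, removing a gene from
#' every task at once -- joint feature selection.
#'
#' @param W Numeric p-by-t matrix.
#' @return Nonnegative scalar.
#' @examples
#' l21_norm(matrix(c(3, 4), 1, 2))  # 5
#' @export
l21_norm <- function(W) {
  W <- as.matrix(W)
  if (length(W) == 0) stop("W must be non-empty", call. = FALSE)
  sum(sqrt(rowSums(W^2)))
}

#' Composite multi-task objective
#'
#' The regularized multi-task objective: the sum over tasks of the mean
#' logistic loss, plus `lambda1 * l21_norm(W)` plus
#' `lambda2 * sum(W^2)` (squared Frobenius norm). All tasks share the
#' predictor matrix, so each task's loss is computed over all n samples.
#'
#' @param tasks A [task_set()].
#' @param W Numeric p-by-t coefficient matrix (or an `rmtl_model`, in which
#'   case `C`, `lambda1`, `lambda2` are taken from it).
#' @param C Numeric length-t intercept vector.
#' @param lambda1 Nonnegative L2,1 penalty strength.
#' @param lambda2 Nonnegative ridge (squared-Frobenius) penalty strength.
#' @return Nonnegative scalar objective value.
#' @export
rmtl_objective <- function(tasks, W, C = NULL, lambda1 = NULL, lambda2 = NULL) {
  stopifnot(inherits(tasks, "task_set"))
  if (inherits(W, "rmtl_model")) {
    model <- W
    W <- model$W; C <- model$C
    lambda1 <- model$lambda1; lambda2 <- model$lambda2
  }
  W <- as.matrix(W)
  t <- ncol(tasks$Y)
  if (nrow(W) != ncol(tasks$X) || ncol(W) != t)
    stop_dims("W", c(ncol(tasks$X), t), dim(W))
  if (length(C) != t) stop_dims("C", t, length(C))
  smooth_loss_value(tasks$X, tasks$Y, W, C) +
    lambda1 * l21_norm(W) + lambda2 * sum(W^2)
}

# Sum over tasks of mean logistic loss (no penalties).
#' @noRd
smooth_loss_value <- function(X, Y, W, C) {
  M <- Y * (X %*% W + matrix(C, nrow(X), length(C), byrow = TRUE))
  sum(softplus(-M)) / nrow(X)
}

#' Gradient of the summed logistic losses
#'
#' Analytic gradient of the task-summed mean logistic loss with respect to
#' the coefficient matrix and intercepts. For task i,
#' `dL/dW_i = -(1/n) sum_k sigmoid(-m_ik) * Y_ik * x_k` where `m_ik` is the
#' signed margin; likewise for the intercept without the `x_k` factor. The
#' ridge term is not included here (see [rmtl_fit()]).
#'
#' @param X Numeric n-by-p predictor matrix.
#' @param Y Numeric n-by-t matrix of +1/-1 responses.
#' @param W Numeric p-by-t coefficient matrix.
#' @param C Numeric length-t intercept vector.
#' @return List with `W` (p-by-t gradient) and `C` (length-t gradient).
#' @export
logistic_loss_grad <- function(X, Y, W, C) {
  X <- as.matrix(X); Y <- as.matrix(Y); W <- as.matrix(W)
  if (nrow(X) != nrow(Y)) stop_dims("Y rows", nrow(X), nrow(Y))
  if (nrow(W) != ncol(X) || ncol(W) != ncol(Y))
    stop_dims("W", c(ncol(X), ncol(Y)), dim(W))
  if (length(C) != ncol(Y)) stop_dims("C", ncol(Y), length(C))
  check_pm1(Y, "Y")
  n <- nrow(X)
  M <- Y * (X %*% W + matrix(C, n, length(C), byrow = TRUE))
  # sigmoid(-M) * Y, computed stably via plogis
  S <- stats::plogis(-M) * Y
  list(W = -crossprod(X, S) / n, C = -colSums(S) / n)
}

#' Row-wise group soft-thresholding (proximal operator of the L2,1 norm)
#'
#' Maps each row r of `W` to `max(0, 1 - tau / ||r||_2) * r`; rows whose
#' norm is at or below `tau` become exactly zero. This is the closed-form
#' proximal operator of `tau * l21_norm(.)`, the step that performs joint
#' feature elimination inside the solver.
#'
#' @param W Numeric p-by-t matrix.
#' @param tau Nonnegative threshold.
#' @return Matrix of the same shape with shrunken rows.
#' @examples
#' prox_l21(matrix(c(3, 4), 1, 2), tau = 1)  # (2.4, 3.2)
#' @export
prox_l21 <- function(W, tau) {
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  W <- as.matrix(W)
  nrm <- sqrt(rowSums(W^2))
  scale <- ifelse(nrm > tau, 1 - tau / nrm, 0)
  scale[nrm == 0] <- 0
  W * scale
}

#' Solver control parameters
#'
#' @param max_iterations Maximum number of outer iterations (default 5000).
#' @param tolerance Relative objective-change stopping threshold
#'   `|f_k - f_{k-1}| / max(1, |f_{k-1}|) < tolerance` (default 1e-6).
#' @param initial_step Initial proximal-gradient step size (default 1).
#' @param backtracking_factor Multiplier in (0, 1) applied to the step when
#'   the backtracking condition fails (default 0.5).
#' @return A list of class `rmtl_control`.
#' @export
rmtl_control <- function(max_iterations = 5000L, tolerance = 1e-6,
                         initial_step = 1, backtracking_factor = 0.5) {
  stopifnot(max_iterations >= 1, tolerance > 0, initial_step > 0,
            backtracking_factor > 0, backtracking_factor < 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, initial_step = initial_step,
                 backtracking_factor = backtracking_factor),
            class = "rmtl_control")
}

#' Fit the L2,1-regularized multi-task logistic model
#'
#' Minimizes the composite objective
#' `sum_i mean_logistic_loss_i + lambda1 * l21(W) + lambda2 * ||W||_F^2`
#' by accelerated proximal gradient (FISTA) with backtracking line search.
#' The smooth part is the summed logistic losses plus the ridge term; the
#' non-smooth L2,1 term is handled by [prox_l21()] applied to `W` only.
#' Intercepts are unpenalized and move by plain gradient steps at the same
#' step size. A monotone variant is used: the accelerated candidate is
#' accepted only when it does not increase the objective, so the recorded
#' objective trace is non-increasing by construction.
#'
#' Initialization is deterministic (`W = 0`, `C = 0`), making fits fully
#' reproducible. Iteration stops when the relative objective change drops
#' below `control$tolerance` or `control$max_iterations` is reached.
#'
#' @param tasks A [task_set()].
#' @param lambda1 Nonnegative strength of the L2,1 row penalty.
#' @param lambda2 Nonnegative strength of the squared-Frobenius penalty.
#' @param control An [rmtl_control()] list.
#' @return An object of class `rmtl_model`: coefficient matrix `W`
#'   (genes x tasks), intercepts `C`, the penalties, `task_names`,
#'   `gene_ids`, and a `trace` list with `objective_values`,
#'   `n_iterations`, `converged`, `tolerance`, `step_sizes`.
#' @examples
#' sim <- simulate_expression(simulation_spec(n_classes = 3,
#'   samples_per_class = 20, n_genes = 40, signal_genes_per_class = 5,
#'   seed = 1))
#' fit <- rmtl_fit(build_tasks(sim$dataset), lambda1 = 1e-3, lambda2 = 1e-4)
#' fit
#' @export
rmtl_fit <- function(tasks, lambda1, lambda2, control = rmtl_control()) {
  stopifnot(inherits(tasks, "task_set"))
  if (lambda1 < 0 || lambda2 < 0)
    stop("penalties must be nonnegative", call. = FALSE)
  X <- tasks$X; Y <- tasks$Y
  if (any(!is.finite(X)))
    stop("predictor matrix contains non-finite values", call. = FALSE)
  p <- ncol(X); t <- ncol(Y)

  # smooth part g(W, C) = summed mean logistic losses + lambda2 * ||W||_F^2
  g_val <- function(W, C) smooth_loss_value(X, Y, W, C) + lambda2 * sum(W^2)
  g_grad <- function(W, C) {
    gr <- logistic_loss_grad(X, Y, W, C)
    gr$W <- gr$W + 2 * lambda2 * W
    gr
  }
  obj <- function(W, C) g_val(W, C) + lambda1 * l21_norm(W)

  W <- matrix(0, p, t); C <- rep(0, t)
  VW <- W; VC <- C                      # extrapolation point
  step <- control$initial_step
  theta <- 1
  f_prev <- obj(W, C)
  objective_values <- f_prev
  step_sizes <- numeric(0)
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(control$max_iterations)) {
    gv <- g_val(VW, VC)
    gr <- g_grad(VW, VC)
    # backtracking: find step with g(z) <= g(v) + <grad, z - v> + ||z-v||^2/(2 step)
    repeat {
      ZW <- prox_l21(VW - step * gr$W, step * lambda1)
      ZC <- VC - step * gr$C
      dW <- ZW - VW; dC <- ZC - VC
      quad <- gv + sum(gr$W * dW) + sum(gr$C * dC) +
        (sum(dW^2) + sum(dC^2)) / (2 * step)
      if (g_val(ZW, ZC) <= quad + 1e-12) break
      step <- step * control$backtracking_factor
      if (step < .Machine$double.eps)
        stop("backtracking line search failed: step underflow", call. = FALSE)
    }
    f_z <- obj(ZW, ZC)
    if (f_z <= f_prev) {
      # monotone acceptance; momentum driven by the candidate point
      theta_new <- (1 + sqrt(1 + 4 * theta^2)) / 2
      VW <- ZW + ((theta - 1) / theta_new) * (ZW - W)
      VC <- ZC + ((theta - 1) / theta_new) * (ZC - C)
      W <- ZW; C <- ZC; theta <- theta_new
      objective_values <- c(objective_values, f_z)
      step_sizes <- c(step_sizes, step)
      rel <- abs(f_z - f_prev) / max(1, abs(f_prev))
      f_prev <- f_z
      if (rel < control$tolerance) { converged <- TRUE; break }
    } else {
      # extrapolation overshot: restart momentum at the current iterate so
      # the next pass is a plain (guaranteed-descent) proximal step
      VW <- W; VC <- C; theta <- 1
      objective_values <- c(objective_values, f_prev)
      step_sizes <- c(step_sizes, step)
    }
  }

  structure(list(W = `dimnames<-`(W, list(tasks$gene_ids, tasks$task_names)),
                 C = stats::setNames(C, tasks$task_names),
                 lambda1 = lambda1, lambda2 = lambda2,
                 task_names = tasks$task_names, gene_ids = tasks$gene_ids,
                 trace = list(objective_values = objective_values,
                              n_iterations = iter, converged = converged,
                              tolerance = control$tolerance,
                              step_sizes = step_sizes)),
            class = "rmtl_model")
}

#' @export
print.rmtl_model <- function(x, ...) {
  nz <- sum(sqrt(rowSums(x$W^2)) > 0)
  cat(sprintf(paste0("rmtl_model: %d genes x %d tasks, lambda1 = %g, ",
                     "lambda2 = %g\n  %d active gene rows; %d iterations, ",
                     "converged: %s, final objective %.6g\n"),
              nrow(x$W), ncol(x$W), x$lambda1, x$lambda2, nz,
              x$trace$n_iterations, x$trace$converged,
              utils::tail(x$trace$objective_values, 1)))
  invisible(x)
}

#' One-vs-rest class probabilities
#'
#' Entry (k, i) is `sigmoid(x_k . W_i + C_i)`: the probability task i
#' assigns to sample k being in its positive class. Rows are NOT
#' normalized across tasks -- each column is an independent one-vs-rest
#' probability.
#'
#' @param object A fitted `rmtl_model`.
#' @param newdata Numeric m-by-p matrix (or `expression_dataset` /
#'   `task_set`) whose gene columns match `object$gene_ids` in order.
#' @param type `"response"` for the m-by-t probability matrix, `"class"`
#'   for predicted labels (see [predict_labels()]).
#' @param ... Unused.
#' @return Probability matrix, or a data frame of labels and
#'   low-confidence flags for `type = "class"`.
#' @export
predict.rmtl_model <- function(object, newdata, type = c("response", "class"),
                               ...) {
  type <- match.arg(type)
  if (inherits(newdata, "expression_dataset") || inherits(newdata, "task_set")) {
    ids <- if (inherits(newdata, "expression_dataset")) newdata$gene_ids else newdata$gene_ids
    if (!identical(ids, object$gene_ids))
      stop("gene order of newdata does not match the model; ",
           "reindex columns to model$gene_ids before predicting", call. = FALSE)
    newdata <- newdata$X
  }
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object$W)) stop_dims("newdata columns", nrow(object$W), ncol(X))
  if (!is.null(colnames(X)) && !identical(colnames(X), object$gene_ids))
    stop("gene order of newdata does not match the model; ",
         "reindex columns to model$gene_ids before predicting", call. = FALSE)
  P <- stats::plogis(X %*% object$W +
                       matrix(object$C, nrow(X), length(object$C), byrow = TRUE))
  colnames(P) <- object$task_names
  rownames(P) <- rownames(X)
  if (type == "response") P else predict_labels(P, object$task_names)
}

#' Assign class labels from one-vs-rest probabilities
#'
#' Each sample receives the class of its maximum-probability task; ties
#' break toward the lowest task index. A sample whose maximum probability
#' does not exceed 0.5 is still assigned the argmax class but flagged
#' low-confidence, so every sample keeps a label and confusion-matrix
#' accounting stays complete.
#'
#' @param proba Numeric m-by-t matrix of probabilities in \[0, 1\].
#' @param task_names Character vector of t class names (defaults to the
#'   matrix column names).
#' @return Data frame with columns `label` and `low_confidence`.
#' @export
predict_labels <- function(proba, task_names = colnames(proba)) {
  proba <- as.matrix(proba)
  if (length(proba) == 0) stop("probability matrix is empty", call. = FALSE)
  if (is.null(task_names)) stop("task_names required", call. = FALSE)
  if (length(task_names) != ncol(proba))
    stop_dims("task_names", ncol(proba), length(task_names))
  best <- max.col(proba, ties.method = "first")
  pmax_val <- proba[cbind(seq_len(nrow(proba)), best)]
  data.frame(label = task_names[best],
             low_confidence = pmax_val <= 0.5,
             row.names = rownames(proba), stringsAsFactors = FALSE)
}

#' Serialize a fitted model to a JSON + TSV bundle
#'
#' Writes `<prefix>.json` (task names, gene ids, penalties, trace summary)
#' plus `<prefix>_W.tsv` and `<prefix>_C.tsv` with coefficients printed at
#' 17 significant digits so the round trip is bit-faithful.
#'
#' @param model A fitted `rmtl_model`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_rmtl_model <- function(model, prefix) {
  stopifnot(inherits(model, "rmtl_model"))
  header <- list(task_names = model$task_names, gene_ids = model$gene_ids,
                 lambda1 = model$lambda1, lambda2 = model$lambda2,
                 trace = list(n_iterations = model$trace$n_iterations,
                              converged = model$trace$converged,
                              tolerance = model$trace$tolerance,
                              final_objective = format_full(
                                utils::tail(model$trace$objective_values, 1))))
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  Wc <- matrix(format_full(model$W), nrow(model$W), ncol(model$W))
  utils::write.table(cbind(gene_id = model$gene_ids,
                           `colnames<-`(Wc, model$task_names)),
                     paste0(prefix, "_W.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(task = model$task_names,
                                intercept = format_full(model$C)),
                     paste0(prefix, "_C.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paste0(prefix, c(".json", "_W.tsv", "_C.tsv")))
}

#' Read a model bundle written by [write_rmtl_model()]
#'
#' @param prefix The path prefix used when writing.
#' @return An `rmtl_model` (trace restored in summary form).
#' @export
read_rmtl_model <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  Wdf <- utils::read.delim(paste0(prefix, "_W.tsv"), check.names = FALSE,
                           colClasses = "character")
  W <- apply(as.matrix(Wdf[, -1, drop = FALSE]), c(1, 2), as.numeric)
  dimnames(W) <- list(Wdf$gene_id, colnames(Wdf)[-1])
  Cdf <- utils::read.delim(paste0(prefix, "_C.tsv"), colClasses = "character")
  C <- stats::setNames(as.numeric(Cdf$intercept), Cdf$task)
  structure(list(W = W, C = C, lambda1 = header$lambda1,
                 lambda2 = header$lambda2,
                 task_names = header$task_names, gene_ids = header$gene_ids,
                 trace = list(objective_values =
                                as.numeric(header$trace$final_objective),
                              n_iterations = header$trace$n_iterations,
                              converged = header$trace$converged,
                              tolerance = header$trace$tolerance,
                              step_sizes = numeric(0))),
            class = "rmtl_model")
}
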