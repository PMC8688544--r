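test_that("logistic loss matches analytic values and a term-by-term oracle", {
  # zero margins: every term is log(1 + e^0) = log 2
  X <- matrix(rnorm(15), 5, 3)
  y <- c(1, -1, 1, -1, 1)
  expect_equal(logistic_loss(X, y, rep(0, 3), 0), log(2))
  # single forced term
  expect_equal(logistic_loss(matrix(1, 1, 1), 1, 10, 0), log(1 + exp(-10)))
  # brute-force elementwise oracle on a random instance
  set.seed(101)
  X <- matrix(rnorm(15), 5, 3)
  y <- sample(c(-1, 1), 5, replace = TRUE)
  w <- rnorm(3); c0 <- rnorm(1)
  oracle <- mean(vapply(1:5, function(k) {
    log(1 + exp(-y[k] * (sum(X[k, ] * w) + c0)))
  }, numeric(1)))
  expect_equal(logistic_loss(X, y, w, c0), oracle, tolerance = 1e-12)
})

test_that("logistic loss is stable at extreme margins and validates input", {
  # a margin of -2000 would overflow exp(); softplus form must stay finite
  expect_equal(logistic_loss(matrix(1), 1, -2000, 0), 2000)
  expect_equal(logistic_loss(matrix(1), 1, 2000, 0), 0)
  expect_error(logistic_loss(matrix(rnorm(6), 2), c(1, 0), rnorm(3), 0), "\\+1")
  expect_error(logistic_loss(matrix(rnorm(6), 2), c(1, -1, 1), rnorm(3), 0),
               "expected")
})

test_that("L2,1 norm equals the row-norm sum", {
  expect_equal(l21_norm(matrix(0, 4, 3)), 0)
  expect_equal(l21_norm(matrix(c(3, 4), 1, 2)), 5)
  set.seed(7)
  W <- matrix(rnorm(24), 6, 4)
  oracle <- sum(vapply(1:6, function(j) sqrt(sum(W[j, ]^2)), numeric(1)))
  expect_equal(l21_norm(W), oracle, tolerance = 1e-12)
})

test_that("the composite objective assembles loss and penalties", {
  set.seed(12)
  X <- matrix(rnorm(32), 8, 4)
  labels <- rep(c("A", "B", "C"), length.out = 8)
  ts <- build_tasks(expression_dataset(X, labels))
  W0 <- matrix(0, 4, 3)
  expect_equal(rmtl_objective(ts, W0, rep(0, 3), 0, 0), 3 * log(2))
  # random point: term-by-term assembly oracle
  W <- matrix(rnorm(12), 4, 3); C <- rnorm(3)
  l1 <- 0.3; l2 <- 0.07
  oracle <- sum(vapply(1:3, function(i) {
    logistic_loss(ts$X, ts$Y[, i], W[, i], C[i])
  }, numeric(1))) + l1 * l21_norm(W) + l2 * sum(W^2)
  expect_equal(rmtl_objective(ts, W, C, l1, l2), oracle, tolerance = 1e-10)
  # penalties vanish at zero strengths
  expect_equal(rmtl_objective(ts, W, C, 0, 0),
               sum(vapply(1:3, function(i)
                 logistic_loss(ts$X, ts$Y[, i], W[, i], C[i]), numeric(1))))
})

test_that("loss gradient matches the symmetric two-point case", {
  X <- matrix(c(1, -1), 2, 1)
  Y <- matrix(c(1, -1), 2, 1)
  g <- logistic_loss_grad(X, Y, matrix(0, 1, 1), 0)
  expect_equal(as.numeric(g$W), -0.5)
  expect_equal(g$C, 0)
})

test_that("loss gradient vanishes when margins saturate", {
  set.seed(21)
  X <- matrix(rnorm(20), 10, 2)
  X[, 1] <- X[, 1] + 0.5 * sign(X[, 1])  # keep margins away from zero
  y <- ifelse(X[, 1] > 0, 1, -1)
  g <- logistic_loss_grad(X, matrix(y, ncol = 1),
                          matrix(c(500, 0), 2, 1), 0)
  expect_lt(sqrt(sum(g$W^2) + g$C^2), 1e-10)
})

test_that("loss gradient matches central finite differences", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(5:20, 1); p <- sample(2:10, 1); t <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(sample(c(-1, 1), n * t, replace = TRUE), n, t)
    W <- matrix(rnorm(p * t, sd = 0.5), p, t); C <- rnorm(t, sd = 0.5)
    f <- function(W, C) {
      sum(vapply(seq_len(t), function(i)
        logistic_loss(X, Y[, i], W[, i], C[i]), numeric(1)))
    }
    g <- logistic_loss_grad(X, Y, W, C)
    h <- 1e-6
    fd_W <- matrix(0, p, t)
    for (j in seq_len(p)) for (i in seq_len(t)) {
      Wp <- W; Wp[j, i] <- W[j, i] + h
      Wm <- W; Wm[j, i] <- W[j, i] - h
      fd_W[j, i] <- (f(Wp, C) - f(Wm, C)) / (2 * h)
    }
    fd_C <- vapply(seq_len(t), function(i) {
      Cp <- C; Cp[i] <- C[i] + h
      Cm <- C; Cm[i] <- C[i] - h
      (f(W, Cp) - f(W, Cm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g$W - fd_W)) / max(1, max(abs(fd_W))), 1e-5)
    expect_lt(max(abs(g$C - fd_C)) / max(1, max(abs(fd_C))), 1e-5)
  }
})

test_that("group soft-thresholding shrinks rows exactly as prescribed", {
  W <- matrix(rnorm(12), 4, 3)
  expect_equal(prox_l21(W, 0), W)
  # norm exactly at the threshold -> zeroed
  expect_equal(as.numeric(prox_l21(matrix(c(0.3, 0.4), 1, 2), 0.5)), c(0, 0))
  # 3-4-5 row shrunk by 1/5
  expect_equal(as.numeric(prox_l21(matrix(c(3, 4), 1, 2), 1)), c(2.4, 3.2))
  expect_error(prox_l21(W, -1), "nonnegative")
  # zero row stays zero
  expect_equal(as.numeric(prox_l21(matrix(0, 1, 2), 0.7)), c(0, 0))
})

test_that("prox output minimizes the proximal objective", {
  # vs a generic numerical minimizer, and vs random candidate points
  set.seed(55)
  for (rep in 1:20) {
    w <- rnorm(4, sd = 2)
    tau <- runif(1, 0, 3)
    prox_obj <- function(u) 0.5 * sum((u - w)^2) + tau * sqrt(sum(u^2))
    mine <- as.numeric(prox_l21(matrix(w, 1), tau))
    o <- optim(w / 2, prox_obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    expect_lte(prox_obj(mine), o$value + 1e-8)
    cand <- matrix(rnorm(4 * 200, sd = 2), ncol = 4)
    expect_true(all(prox_obj(mine) <= apply(cand, 1, prox_obj) + 1e-12))
  }
})

test_that("huge lambda1 yields the intercept-only model with log-odds intercepts", {
  sim <- small_sim()
  ts <- build_tasks(sim$dataset)
  g0 <- logistic_loss_grad(ts$X, ts$Y, matrix(0, ncol(ts$X), ncol(ts$Y)),
                           rep(0, ncol(ts$Y)))
  big <- 10 * max(sqrt(rowSums(g0$W^2)))
  m <- rmtl_fit(ts, big, 0, rmtl_control(tolerance = 1e-12))
  expect_true(all(m$W == 0))
  pos <- colSums(ts$Y == 1); neg <- colSums(ts$Y == -1)
  expect_equal(unname(m$C), log(pos / neg), ignore_attr = TRUE,
               tolerance = 1e-4)
  # balanced binary task: intercept exactly 0
  Xb <- matrix(rnorm(20), 10, 2)
  tsb <- task_set(Xb, matrix(rep(c(1, -1), 5), ncol = 1), "pos")
  mb <- rmtl_fit(tsb, 100, 0, rmtl_control(tolerance = 1e-12))
  expect_lt(abs(mb$C), 1e-6)
})

test_that("single-task fit matches independent optimizers", {
  set.seed(3)
  n <- 40; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- ifelse(X[, 1] - X[, 2] + rnorm(n, 0, 0.8) > 0, 1, -1)
  ts <- task_set(X, matrix(y, ncol = 1), "pos")
  ctrl <- rmtl_control(tolerance = 1e-12, max_iterations = 20000)
  # smooth case: BFGS on the identical scalar objective
  l2 <- 0.01
  m0 <- rmtl_fit(ts, 0, l2, ctrl)
  fn <- function(par) logistic_loss(X, y, par[1:p], par[p + 1]) +
    l2 * sum(par[1:p]^2)
  o <- optim(rep(0, p + 1), fn, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(rmtl_objective(ts, m0) - o$value), 1e-6)
  # composite case: elastic-net logistic regression as the oracle
  skip_if_not_installed("glmnet")
  l1 <- 0.02
  m1 <- rmtl_fit(ts, l1, l2, ctrl)
  lam <- l1 + 2 * l2
  g <- glmnet::glmnet(X, factor(y), family = "binomial", alpha = l1 / lam,
                      lambda = lam, standardize = FALSE, thresh = 1e-14,
                      maxit = 1e6)
  cf <- as.numeric(stats::coef(g))
  obj_oracle <- logistic_loss(X, y, cf[-1], cf[1]) +
    l1 * sum(abs(cf[-1])) + l2 * sum(cf[-1]^2)
  expect_lt(abs(rmtl_objective(ts, m1) - obj_oracle), 1e-6)
})

test_that("the objective trace is monotone and the solver converges", {
  m <- std_fit()
  ov <- m$trace$objective_values
  expect_true(all(diff(ov) <= 0))
  expect_true(m$trace$converged)
  expect_lte(m$trace$n_iterations, 5000)
  expect_equal(ov[1], 6 * log(2))  # deterministic zero start
})

test_that("row sparsity is non-decreasing in lambda1", {
  ts <- build_tasks(small_sim()$dataset)
  zeros <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1, 1), function(l1) {
    sum(rowSums(rmtl_fit(ts, l1, 1e-5)$W^2) == 0)
  }, numeric(1))
  expect_true(all(diff(zeros) >= 0))
})

test_that("permuting gene order permutes W rows and preserves the objective", {
  sim <- small_sim()
  ts <- build_tasks(sim$dataset)
  m <- rmtl_fit(ts, 1e-3, 1e-4)
  set.seed(9)
  perm <- sample(ncol(ts$X))
  dperm <- subset_dataset(sim$dataset, genes = perm)
  mp <- rmtl_fit(build_tasks(dperm), 1e-3, 1e-4)
  expect_equal(unname(mp$W), unname(m$W[perm, ]), tolerance = 1e-6)
  expect_equal(rmtl_objective(build_tasks(dperm), mp),
               rmtl_objective(ts, m), tolerance = 1e-8)
})

test_that("probability prediction is an elementwise sigmoid", {
  sim <- small_sim()
  ts <- build_tasks(sim$dataset)
  p <- ncol(ts$X); t <- ncol(ts$Y)
  m <- rmtl_fit(ts, 1e-3, 1e-4, rmtl_control(max_iterations = 5))
  m$W[] <- 0; m$C[] <- 0
  expect_true(all(predict(m, ts$X) == 0.5))
  m$C[2] <- 50
  expect_equal(unname(predict(m, ts$X)[, 2]), rep(1, nrow(ts$X)))
  # random model: sigmoid oracle
  set.seed(14)
  m$W[] <- rnorm(p * t); m$C[] <- rnorm(t)
  P <- predict(m, ts$X)
  oracle <- 1 / (1 + exp(-(ts$X %*% m$W +
                             matrix(m$C, nrow(ts$X), t, byrow = TRUE))))
  expect_equal(unname(P), unname(oracle), tolerance = 1e-12)
  # mismatched gene order is refused
  Xs <- ts$X[, rev(seq_len(p))]
  expect_error(predict(m, Xs), "reindex")
})

test_that("label assignment takes the argmax with deterministic ties and flags", {
  pr <- rbind(c(0.9, 0.2, 0.1), c(0.4, 0.4, 0.4), c(0.2, 0.6, 0.6))
  out <- predict_labels(pr, c("A", "B", "C"))
  expect_equal(out$label, c("A", "A", "B"))
  expect_equal(out$low_confidence, c(FALSE, TRUE, FALSE))
  expect_error(predict_labels(matrix(numeric(0), 0, 0), character(0)), "empty")
})

test_that("a model fit on well-separated data classifies held-out samples", {
  sim <- std_sim()
  split <- stratified_split(sim$dataset, 0.2, 77)
  m <- rmtl_fit(build_tasks(split$train), 1e-4, 1e-5)
  pred <- predict_labels(predict(m, split$test$X))
  expect_gte(mean(pred$label == split$test$labels), 0.95)
})

test_that("model serialization round-trips bit-faithfully", {
  m <- rmtl_fit(build_tasks(small_sim()$dataset), 1e-3, 1e-4,
                rmtl_control(max_iterations = 50))
  prefix <- file.path(withr::local_tempdir(), "model")
  write_rmtl_model(m, prefix)
  m2 <- read_rmtl_model(prefix)
  expect_identical(unname(m2$W), unname(m$W))
  expect_identical(unname(m2$C), unname(m$C))
  expect_identical(m2$task_names, m$task_names)
  expect_identical(m2$gene_ids, m$gene_ids)
  expect_identical(m2$lambda1, m$lambda1)
})
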