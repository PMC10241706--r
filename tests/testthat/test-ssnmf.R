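test_that("objective evaluates the two Frobenius terms exactly", {
  inst <- exact_factorization_instance(m = 20, n = 12)
  model0 <- list(A = inst$A0, B = diag(4), S = inst$L,
                 config = ssnmf_config(k = 4, lam = 1))
  expect_equal(ssnmf_objective(inst$X, inst$L, model0), 0)

  set.seed(2)
  X <- matrix(runif(20 * 12), 20, 12)
  model0$config$lam <- 0
  expect_equal(ssnmf_objective(X, inst$L, model0),
               sum((X - inst$A0 %*% inst$L)^2))

  z <- list(A = matrix(0, 2, 1), B = matrix(0, 4, 1), S = matrix(0, 1, 2),
            config = ssnmf_config(k = 1, lam = 1))
  expect_equal(ssnmf_objective(matrix(1, 2, 2), matrix(0, 4, 2), z), 4)

  expect_error(ssnmf_objective(matrix(1, 3, 2), matrix(0, 4, 2), model0),
               "dimension mismatch")
})

test_that("multiplicative updates are monotone and respect nonnegativity", {
  set.seed(31)
  X <- matrix(runif(50 * 40), 50, 40)
  labels <- factor(rep(c("LumA", "LumB", "HER2", "Basal"), 10))
  L <- onehot_matrix(labels)
  fit <- fit_ssnmf(X, L, ssnmf_config(k = 6, lam = 1, max_iter = 300,
                                      tol = 1e-12, seed = 5))
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * tr[-length(tr)]))
  expect_true(all(fit$A >= 0) && all(fit$B >= 0) && all(fit$S >= 0))

  expect_error(fit_ssnmf(-X, L, ssnmf_config(k = 2)), "domain error")
  expect_error(fit_ssnmf(X[, 1:3], L[, 1:3], ssnmf_config(k = 5)),
               "rank error")
})

test_that("the exact-factorization optimum is recovered", {
  inst <- exact_factorization_instance(m = 30, n = 24, seed = 3)
  fit <- fit_ssnmf(inst$X, inst$L,
                   ssnmf_config(k = 4, lam = 1, max_iter = 30000,
                                tol = 1e-15, seed = 1))
  expect_lt(fit$objective_trace[length(fit$objective_trace)],
            1e-6 * fit$objective_trace[1])
})

test_that("rank-1 unsupervised fit matches the SVD residual oracle", {
  set.seed(17)
  for (rep in 1:3) {
    X <- matrix(runif(6, 0.2, 2), 3, 2)
    fit <- fit_ssnmf(X, matrix(0, 4, 2),
                     ssnmf_config(k = 1, lam = 0, max_iter = 5000,
                                  tol = 1e-13, seed = rep))
    oracle <- sum(svd(X)$d[-1]^2)
    expect_equal(fit$objective_trace[length(fit$objective_trace)], oracle,
                 tolerance = 1e-6)
  }
})

test_that("held-out NNLS inference recovers noiseless coefficients", {
  set.seed(23)
  A <- matrix(runif(20 * 4, 0.1, 1), 20, 4)
  model <- list(A = A, B = diag(4), S = NULL, config = ssnmf_config(k = 4))
  # canonical columns
  s_hat <- infer_coefficients(A[, 2, drop = FALSE], model)
  expect_equal(as.vector(s_hat), c(0, 1, 0, 0), tolerance = 1e-8)
  # zero input -> zero coefficients
  expect_equal(as.vector(infer_coefficients(matrix(0, 20, 1), model)),
               rep(0, 4))
  # random nonnegative combination
  s0 <- runif(4)
  s_hat <- infer_coefficients(A %*% s0, model)
  expect_equal(as.vector(s_hat), s0, tolerance = 1e-6)
  expect_error(infer_coefficients(matrix(1, 5, 1), model), "dimension")
})

test_that("label prediction takes the argmax with first-index ties", {
  model <- list(A = NULL, B = diag(4), config = ssnmf_config(k = 4))
  expect_equal(predict_labels(model, matrix(c(0.7, 0.1, 0.1, 0.1))), 1L)
  expect_equal(predict_labels(model, matrix(c(0.2, 0.5, 0.2, 0.1))), 2L)
  expect_equal(predict_labels(model, matrix(0, 4, 1)), 1L)
})

test_that("objective scales as c^2 when X scales by c and lambda by c^2", {
  inst <- exact_factorization_instance(m = 15, n = 12, seed = 9)
  set.seed(4)
  model <- list(A = matrix(runif(15 * 4), 15, 4), B = matrix(runif(16), 4, 4),
                S = matrix(runif(4 * 12), 4, 12),
                config = ssnmf_config(k = 4, lam = 2))
  cc <- 3.7
  scaled <- model
  scaled$A <- cc * model$A
  scaled$config$lam <- cc^2 * model$config$lam
  expect_equal(ssnmf_objective(cc * inst$X, inst$L, scaled),
               cc^2 * ssnmf_objective(inst$X, inst$L, model),
               tolerance = 1e-12)
})

test_that("fits are bit-identical under a fixed seed", {
  inst <- exact_factorization_instance(m = 25, n = 20, seed = 6)
  cfg <- ssnmf_config(k = 4, lam = 1, max_iter = 100, seed = 42)
  f1 <- fit_ssnmf(inst$X, inst$L, cfg)
  f2 <- fit_ssnmf(inst$X, inst$L, cfg)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$S, f2$S)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("cross-validation selects a singleton grid and scores chance on permuted labels", {
  b <- reference_cohort(n = 160, m = 120, k_true = 4, separation = 10,
                        noise_sd = 0.05, seed = 19)
  X <- b$expression$values
  L <- b$onehot
  sel <- select_hyperparameters(X, L, k_grid = 4, lam_grid = 1, folds = 5,
                                seed = 2, max_iter = 300)
  expect_equal(sel$k, 4)
  expect_equal(sel$lam, 1)
  expect_equal(nrow(sel$cv_table), 1L)
  expect_gte(sel$accuracy, 0.9)   # recoverable structure

  set.seed(8)
  Lperm <- L[, sample(ncol(L))]
  selp <- select_hyperparameters(X, Lperm, k_grid = 4, lam_grid = 1,
                                 folds = 5, seed = 2, max_iter = 300)
  expect_lt(abs(selp$accuracy - 0.25), 0.1)
})
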