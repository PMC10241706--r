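# Semi-supervised non-negative matrix factorization.
#
# Objective:  || X - A S ||_F^2  +  lambda || L - B S ||_F^2,
#             A, B, S elementwise >= 0,
# where X (m x n) is nonnegative expression, L (4 x n) one-hot subtype
# labels, A (m x k) the metagenes, S (k x n) the mixing coefficients, and
# B (4 x k) the label basis. Solved with Lee-Seung multiplicative updates
# on the augmented system [X; sqrt(lambda) L] ~ [A; sqrt(lambda) B] S,
# which reduces to separate A/B updates and a combined S update and keeps
# the objective monotone non-increasing.

#' ssNMF configuration
#'
#' @param k Number of metagenes (>= 1).
#' @param lam Tradeoff between data and label reconstruction (\code{lam > 0};
#'   \code{lam = 0} gives plain unsupervised NMF).
#' @param max_iter Iteration cap (default 2000).
#' @param tol Convergence tolerance: relative objective change over a
#'   10-iteration window (default 1e-5).
#' @param seed Seed for the random nonnegative initialization.
#' @param eps Stabilizer added to update denominators (default 1e-10).
#' @return A list of class \code{ssnmf_config}.
#' @export
ssnmf_config <- function(k, lam = 1, max_iter = 2000L, tol = 1e-5,
                         seed = 1L, eps = 1e-10) {
  if (k < 1L) stop("k must be >= 1")
  if (lam < 0) stop("lam must be nonnegative")
  if (tol <= 0 || eps <= 0) stop("tol and eps must be positive")
  structure(list(k = as.integer(k), lam = lam, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed), eps = eps),
            class = "ssnmf_config")
}

#' Evaluate the ssNMF objective
#'
#' @param X m x n data matrix.
#' @param L 4 x n label matrix (ignored when \code{lam = 0}; pass a zero
#'   matrix if unavailable).
#' @param model An \code{ssnmf_model}, or a list with \code{A}, \code{B},
#'   \code{S} and \code{config$lam}.
#' @return The scalar objective value.
#' @export
ssnmf_objective <- function(X, L, model) {
  A <- model$A; B <- model$B; S <- model$S
  lam <- model$config$lam
  if (nrow(A) != nrow(X) || ncol(S) != ncol(X))
    stop("dimension mismatch between X and the model factors")
  obj <- sum((X - A %*% S)^2)
  if (lam > 0) {
    if (nrow(B) != nrow(L) || ncol(S) != ncol(L))
      stop("dimension mismatch between L and the model factors")
    obj <- obj + lam * sum((L - B %*% S)^2)
  }
  obj
}

#' Fit semi-supervised NMF by multiplicative updates
#'
#' Minimizes \code{||X - AS||_F^2 + lam ||L - BS||_F^2} over nonnegative
#' factors. Factors are initialized uniform(0, 1) scaled by
#' \code{sqrt(mean(X) / k)} from the config seed, so runs are reproducible.
#' The strict positivity of the formal constraint is implemented as
#' nonnegativity with an \code{eps}-stabilized denominator; exact zeros can
#' occur and lock (standard multiplicative-update behavior).
#'
#' Convergence: stop when the relative objective change across a
#' 10-iteration window falls below \code{tol}, or at \code{max_iter}.
#'
#' @param X Nonnegative m x n matrix.
#' @param L 4 x n one-hot label matrix (columns sum to 1). Ignored when
#'   \code{config$lam == 0}.
#' @param config An \code{\link{ssnmf_config}}.
#' @return An object of class \code{ssnmf_model}: \code{A} (m x k),
#'   \code{B} (4 x k), \code{S} (k x n), \code{config},
#'   \code{objective_trace}, \code{converged}, \code{iterations}.
#' @export
fit_ssnmf <- function(X, L, config) {
  stopifnot(inherits(config, "ssnmf_config"))
  X <- as.matrix(X)
  if (any(X < 0)) stop("domain error: X has negative entries")
  m <- nrow(X); n <- ncol(X); k <- config$k
  if (k > n) stop("rank error: k (", k, ") exceeds sample count (", n, ")")
  lam <- config$lam; eps <- config$eps
  supervised <- lam > 0
  if (supervised) {
    L <- as.matrix(L)
    if (ncol(L) != n) stop("L column count must match X")
    if (any(L < 0)) stop("L must be nonnegative")
  }
  set.seed(config$seed)
  scale0 <- sqrt(max(mean(X), eps) / k)
  A <- matrix(stats::runif(m * k), m, k) * scale0
  S <- matrix(stats::runif(k * n), k, n) * scale0
  B <- matrix(stats::runif(4L * k), 4L, k) *
    if (supervised) sqrt(max(mean(L), eps) / k) else scale0
  model <- list(A = A, B = B, S = S, config = config)
  trace <- numeric(config$max_iter + 1L)
  trace[1L] <- ssnmf_objective(X, if (supervised) L else NULL, model)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    # S update couples both terms; A and B updates decouple by row block.
    StS_num <- crossprod(A, X)               # k x n
    StS_den <- crossprod(A) %*% S            # k x n
    if (supervised) {
      StS_num <- StS_num + lam * crossprod(B, L)
      StS_den <- StS_den + lam * crossprod(B) %*% S
    }
    S <- S * StS_num / (StS_den + eps)
    SSt <- tcrossprod(S)                     # k x k
    A <- A * (X %*% t(S)) / (A %*% SSt + eps)
    if (supervised) B <- B * (L %*% t(S)) / (B %*% SSt + eps)
    model$A <- A; model$B <- B; model$S <- S
    trace[it + 1L] <- ssnmf_objective(X, if (supervised) L else NULL, model)
    if (it >= 10L) {
      prev <- trace[it - 9L]
      if (prev <= 0 ||
          abs(prev - trace[it + 1L]) / prev < config$tol) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(A = A, B = B, S = S, config = config,
                 objective_trace = trace[seq_len(it + 1L)],
                 converged = converged, iterations = it),
            class = "ssnmf_model")
}

#' @export
print.ssnmf_model <- function(x, ...) {
  cat(sprintf(paste0("ssnmf_model: %d genes, %d samples, k = %d, lambda = %g\n",
                     "  objective %.6g after %d iterations (%s)\n"),
              nrow(x$A), ncol(x$S), x$config$k, x$config$lam,
              x$objective_trace[length(x$objective_trace)], x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Infer mixing coefficients for held-out samples
#'
#' Held-out labels are unknown at prediction time, so the label term is
#' dropped and each new column solves the nonnegative least-squares problem
#' \code{min ||x - A s||^2, s >= 0} against the trained metagene basis.
#'
#' @param X_new Nonnegative m x n_new matrix over the training genes.
#' @param model A fitted \code{ssnmf_model}.
#' @return A k x n_new nonnegative coefficient matrix.
#' @export
infer_coefficients <- function(X_new, model) {
  X_new <- as.matrix(X_new)
  if (nrow(X_new) != nrow(model$A))
    stop("dimension mismatch: X_new rows must match the training genes")
  k <- ncol(model$A)
  S_new <- matrix(0, nrow = k, ncol = ncol(X_new))
  for (j in seq_len(ncol(X_new))) {
    x <- X_new[, j]
    if (all(x == 0)) next
    S_new[, j] <- pracma::lsqnonneg(model$A, x)$x
  }
  S_new
}

#' Predict subtype labels from mixing coefficients
#'
#' The label reconstruction \code{B S} scores each of the four subtypes per
#' sample; the prediction is the argmax, ties resolved to the lowest class
#' index.
#'
#' @param model A fitted \code{ssnmf_model}.
#' @param S_cols k x n' coefficient matrix.
#' @return Integer vector of class indices in 1..4 (1 = LumA, 2 = LumB,
#'   3 = HER2, 4 = Basal).
#' @export
predict_labels <- function(model, S_cols) {
  S_cols <- as.matrix(S_cols)
  if (nrow(S_cols) != ncol(model$B))
    stop("dimension mismatch: S_cols rows must equal k")
  scores <- model$B %*% S_cols
  apply(scores, 2L, which.max)   # which.max takes the first maximum: lowest index
}

#' Select (k, lambda) by stratified cross-validated label accuracy
#'
#' For each grid pair, fits ssNMF on the training folds, infers held-out
#' coefficients by NNLS (labels withheld), predicts subtypes via
#' \code{B S}, and averages the per-fold accuracy. Folds are stratified by
#' subtype from the seed. The winner maximizes mean accuracy; ties go to
#' the smaller \code{k}, then the smaller \code{lambda}.
#'
#' @param X Nonnegative m x n matrix.
#' @param L 4 x n one-hot label matrix.
#' @param k_grid,lam_grid Candidate values.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed governing fold assignment and fit initializations.
#' @param ... Further arguments to \code{\link{ssnmf_config}} (e.g.
#'   \code{max_iter}, \code{tol}).
#' @return A list: \code{k}, \code{lam}, \code{accuracy} (mean CV accuracy
#'   of the winner), and \code{cv_table} (data.frame of k, lam,
#'   mean_accuracy, per-fold accuracies).
#' @export
select_hyperparameters <- function(X, L, k_grid = c(4L, 8L, 12L),
                                   lam_grid = c(0.1, 1, 10), folds = 5L,
                                   seed = 1L, ...) {
  X <- as.matrix(X); L <- as.matrix(L)
  n <- ncol(X)
  if (length(k_grid) == 0L || length(lam_grid) == 0L) stop("empty grid")
  if (n < folds) stop("fewer samples than folds")
  cls <- apply(L, 2L, which.max)
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cl in unique(cls)) {
    idx <- sample(which(cls == cl))
    fold[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  for (f in seq_len(folds))
    if (length(unique(cls[fold != f])) < length(unique(cls)))
      stop("stratification error: a class is absent from a training split")
  grid <- expand.grid(k = k_grid, lam = lam_grid)
  acc_mat <- matrix(NA_real_, nrow = nrow(grid), ncol = folds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(folds)) {
      tr <- fold != f
      cfg <- ssnmf_config(k = grid$k[g], lam = grid$lam[g],
                          seed = seed + 1000L * f, ...)
      fit <- fit_ssnmf(X[, tr, drop = FALSE], L[, tr, drop = FALSE], cfg)
      S_te <- infer_coefficients(X[, !tr, drop = FALSE], fit)
      pred <- predict_labels(fit, S_te)
      acc_mat[g, f] <- mean(pred == cls[!tr])
    }
  }
  mean_acc <- rowMeans(acc_mat)
  ord <- order(-mean_acc, grid$k, grid$lam)
  best <- ord[1L]
  cv_table <- cbind(grid, mean_accuracy = mean_acc,
                    as.data.frame(acc_mat))
  names(cv_table)[-(1:3)] <- paste0("fold", seq_len(folds))
  list(k = grid$k[best], lam = grid$lam[best], accuracy = mean_acc[best],
       cv_table = cv_table)
}

#' Write a fitted model to a directory
#'
#' Emits factor TSVs (A, B, S), a config JSON and the objective trace CSV.
#'
#' @param model A fitted \code{ssnmf_model}.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_ssnmf_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(A = file.path(dir, "A.tsv"), B = file.path(dir, "B.tsv"),
             S = file.path(dir, "S.tsv"),
             config = file.path(dir, "config.json"),
             trace = file.path(dir, "objective_trace.csv"))
  for (f in c("A", "B", "S"))
    utils::write.table(model[[f]], paths[[f]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(model$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(iteration = seq_along(model$objective_trace) - 1L,
                              objective = model$objective_trace),
                   paths[["trace"]], row.names = FALSE)
  invisible(paths)
}
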