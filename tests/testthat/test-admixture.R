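test_that("proportions normalize the label reconstruction columnwise", {
  model <- list(B = diag(4), S = cbind(c(2, 1, 1, 0), c(0, 0, 0, 5)),
                config = ssnmf_config(k = 4))
  P <- admixture_proportions(model, sample_ids = c("a", "b"))
  expect_equal(unname(P[, "a"]), c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(P[, "b"]), c(0, 0, 0, 1))
  model$S <- cbind(model$S, zero = c(0, 0, 0, 0))
  expect_error(admixture_proportions(model, sample_ids = c("a", "b", "z")),
               "degenerate sample.*z")
})

test_that("entropy hits its known anchors and rejects bad vectors", {
  expect_equal(shannon_entropy(c(0.25, 0.25, 0.25, 0.25)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), 1)
  expect_error(shannon_entropy(c(0.5, 0.2, 0.2, 0.2)), "sum")
  expect_error(shannon_entropy(c(-0.1, 0.4, 0.4, 0.3)), "nonnegative")
})

test_that("entropy decreases in the dominant proportion and peaks at uniform", {
  # fixed remaining-mass split: the other three share equally
  ps <- seq(0.25, 1, by = 0.01)
  ent <- vapply(ps, function(p) shannon_entropy(c(p, rep((1 - p) / 3, 3))),
                numeric(1))
  expect_true(all(diff(ent) <= 1e-12))
  expect_equal(max(ent), 2)
  # 2 bits only at the uniform vector
  expect_lt(shannon_entropy(c(0.26, rep(0.74 / 3, 3))), 2)
})

test_that("quartile splitter follows the remainder-to-low rule and stable ties", {
  expect_equal(quartile_stratify(1:8), rep(1:4, each = 2))
  expect_equal(as.integer(table(quartile_stratify(1:10))), c(3L, 3L, 2L, 2L))
  expect_equal(quartile_stratify(rep(1, 8)), rep(1:4, each = 2))
  expect_error(quartile_stratify(1:3), "at least")
  # permutation then unpermutation leaves strata unchanged
  set.seed(12)
  v <- rnorm(37)
  perm <- sample(37)
  q <- quartile_stratify(v)
  qp <- quartile_stratify(v[perm])
  expect_equal(qp[order(perm)][order(v)], q[order(v)])
})

test_that("eQ4 sets are exclusive and pairwise disjoint", {
  # 4 samples, each top-quartile for exactly one subtype
  P <- diag(4) * 0.7 + 0.1
  rownames(P) <- c("LumA", "LumB", "HER2", "Basal")
  eq <- exclusive_top_quartile(P)
  expect_equal(as.character(eq$eq4), c("LumA", "LumB", "HER2", "Basal"))

  # a sample top-quartile for two subtypes gets none
  P2 <- cbind(c(0.40, 0.40, 0.1, 0.1), c(0.30, 0.30, 0.2, 0.2),
              c(0.20, 0.20, 0.3, 0.3), c(0.10, 0.10, 0.4, 0.4),
              c(0.50, 0.50, 0.0, 0.0))
  rownames(P2) <- rownames(P)
  eq2 <- exclusive_top_quartile(P2)
  expect_equal(as.character(eq2$eq4[5]), "none")   # top for LumA and LumB

  # disjointness on random draws
  set.seed(3)
  for (i in 1:5) {
    M <- matrix(rgamma(4 * 40, 1), 4, 40)
    M <- sweep(M, 2, colSums(M), "/")
    rownames(M) <- rownames(P)
    eqr <- exclusive_top_quartile(M)$eq4
    assigned <- eqr[eqr != "none"]
    tq <- exclusive_top_quartile(M)$top_quartile
    # each eQ4 sample is in exactly one subtype's top quartile
    expect_true(all(colSums(tq)[eqr != "none"] == 1))
  }
})

test_that("DRC matches a direct covariance-inversion oracle", {
  cm <- cbind(LumA = rep(0, 10), LumB = rep(2, 10),
              HER2 = rep(-2, 10), Basal = rep(4, 10))
  rownames(cm) <- paste0("g", 1:10)
  # identity covariance, engineered distances: own 1, nearest alternate 2
  x <- cm[, "LumA"]; x[1] <- 1          # distance 1 from LumA
  cm2 <- cm; cm2[, "LumB"] <- x; cm2[, "LumB"][1] <- 3  # distance 2 from x
  cm2[, "HER2"] <- 50; cm2[, "Basal"] <- -50
  expect_equal(distance_ratio_criteria(x, cm2, diag(10), "LumA"), 0.5)
  expect_equal(distance_ratio_criteria(cm[, "HER2"], cm, diag(10), "HER2"), 0)

  set.seed(41)
  for (i in 1:20) {
    S <- crossprod(matrix(rnorm(100), 10, 10)) + diag(10) * 0.5
    cents <- matrix(rnorm(40), 10, 4,
                    dimnames = list(NULL, colnames(cm)))
    x <- rnorm(10)
    Sinv <- solve(S)
    d <- sqrt(apply(cents, 2, function(mu) t(x - mu) %*% Sinv %*% (x - mu)))
    oracle <- d["LumB"] / min(d[-2])
    expect_equal(distance_ratio_criteria(x, cents, S, "LumB"),
                 unname(oracle), tolerance = 1e-10)
  }
})

test_that("pooled covariance is shrunk toward its diagonal", {
  set.seed(9)
  X <- rbind(matrix(rnorm(200), 40, 5), matrix(rnorm(200, 2), 40, 5))
  cls <- rep(c("a", "b"), each = 40)
  S0 <- pooled_covariance(X, cls, gamma = 0)
  S1 <- pooled_covariance(X, cls, gamma = 1 - 1e-9)
  expect_equal(diag(S0), diag(S1), tolerance = 1e-6)
  expect_lt(max(abs(S1[upper.tri(S1)])), 1e-6)
  expect_error(pooled_covariance(X[1, , drop = FALSE], "a"), "samples")
})

test_that("histograms cover the range with conserved counts", {
  centers <- (seq_len(100) - 0.5) / 100
  h <- proportion_histogram(centers, bins = 100)
  expect_true(all(h$count == 1))
  expect_equal(sum(h$count), 100)

  h2 <- proportion_histogram(c(0, 1), bins = 2)
  expect_equal(h2$count, c(1, 1))

  set.seed(2)
  v <- runif(77)
  expect_equal(sum(proportion_histogram(v)$count), 77)

  hc <- proportion_histogram(rep(0.4, 5))
  expect_true(attr(hc, "degenerate"))
  expect_equal(hc$count, 5)
})

test_that("the admixture table assembles consistent per-sample metrics", {
  set.seed(14)
  M <- matrix(rgamma(4 * 24, 1), 4, 24)
  M <- sweep(M, 2, colSums(M), "/")
  rownames(M) <- c("LumA", "LumB", "HER2", "Basal")
  tab <- admixture_table(M)
  expect_equal(nrow(tab), 24L)
  expect_equal(tab$pLumA + tab$pLumB + tab$pHER2 + tab$pBasal,
               rep(1, 24), tolerance = 1e-9)
  expect_true(all(tab$entropy_bits >= 0 & tab$entropy_bits <= 2))
  expect_equal(sort(unique(tab$purity_quartile)), 1:4)
})
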