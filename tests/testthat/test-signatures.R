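make_expr <- function(vals, genes, samples = paste0("s", seq_len(ncol(vals)))) {
  expr_matrix(vals, gene_ids = genes, sample_ids = samples)
}

test_that("packaged signature definitions parse and validate", {
  for (nm in c("proliferation_pam50", "ror_pam50", "oncotype_dx", "mammaprint")) {
    sig <- read_signature(signature_fixture(nm))
    expect_s3_class(sig, "signature_definition")
    expect_gt(length(sig$genes), 0)
  }
  onc <- read_signature(signature_fixture("oncotype_dx"))
  expect_equal(onc$risk_cutpoints, c(18, 31))
  mp <- read_signature(signature_fixture("mammaprint"))
  expect_equal(length(mp$genes), 70L)
})

test_that("gene-set mean score is the plain mean, tolerant to missing genes", {
  sig <- read_signature(signature_fixture("proliferation_pam50"))
  vals <- matrix(8.5, nrow = 11, ncol = 3)
  ex <- make_expr(vals, sig$genes)
  expect_equal(unname(score_mean_of_genes(ex, sig)), rep(8.5, 3))

  # one of 11 missing: mean over the 10 present, with a warning
  vals10 <- matrix(seq_len(30) + 0, nrow = 10)
  ex10 <- make_expr(vals10, sig$genes[-1])
  expect_warning(sc <- score_mean_of_genes(ex10, sig), "missing")
  expect_equal(unname(sc), colMeans(vals10))

  # linear in a constant shift
  ex_c <- ex10; ex_c$values <- ex10$values + 3
  expect_equal(suppressWarnings(score_mean_of_genes(ex_c, sig)),
               suppressWarnings(score_mean_of_genes(ex10, sig)) + 3)

  # coverage error below 50%
  ex4 <- make_expr(matrix(1, 4, 2), sig$genes[1:4])
  expect_error(score_mean_of_genes(ex4, sig), "coverage")
})

test_that("centroid-combination score is linear in its coefficients", {
  sig <- read_signature(signature_fixture("ror_pam50"))
  sig$scale_mult <- NULL; sig$scale_add <- NULL
  corr <- matrix(0, 4, 3, dimnames = list(c("LumA", "LumB", "HER2", "Basal"),
                                          paste0("s", 1:3)))
  expect_equal(unname(score_centroid_combination(NULL, NULL, sig,
                                                 correlations = corr)),
               rep(0, 3))
  sig1 <- sig
  sig1$coefficients <- list(LumA = 1, LumB = 0, HER2 = 0, Basal = 0)
  corr1 <- corr; corr1["LumA", ] <- c(1, 0.5, -0.2)
  expect_equal(unname(score_centroid_combination(NULL, NULL, sig1,
                                                 correlations = corr1)),
               c(1, 0.5, -0.2))
  sig2 <- sig
  sig2$coefficients <- lapply(sig$coefficients, function(v) 2 * v)
  set.seed(6)
  corr_r <- matrix(runif(12, -1, 1), 4, 3, dimnames = dimnames(corr))
  expect_equal(score_centroid_combination(NULL, NULL, sig2, correlations = corr_r),
               2 * score_centroid_combination(NULL, NULL, sig, correlations = corr_r))
})

test_that("grouped linear score honors coefficients, floors and cutpoints", {
  sig <- list(name = "toy", kind = "grouped_linear_score",
              genes = c("a", "b", "c"),
              groups = list(a = "g1", b = "g1", c = "g2"),
              coefficients = list(g1 = 0.5, g2 = -0.25),
              clipping = list(g2 = 0),
              intercept = 1,
              risk_cutpoints = c(2, 3),
              risk_labels = c("low", "mid", "high"))
  class(sig) <- "signature_definition"
  vals <- rbind(a = c(2, 2), b = c(4, 4), c = c(-8, 4))
  ex <- make_expr(vals, rownames(vals))
  out <- score_grouped_linear(ex, sig)
  # s1: g1 mean 3, g2 floored at 0 -> 1 + 1.5 - 0 = 2.5 -> mid
  # s2: g1 mean 3, g2 4           -> 1 + 1.5 - 1 = 1.5 -> low
  expect_equal(out$score, c(2.5, 1.5))
  expect_equal(as.character(out$risk), c("mid", "low"))

  # +1 on the positively weighted group's genes moves the score by its coef
  ex_up <- ex; ex_up$values[c("a", "b"), ] <- ex$values[c("a", "b"), ] + 1
  expect_equal(score_grouped_linear(ex_up, sig)$score, out$score + 0.5)

  # a score exactly at a cutpoint lands in the higher category
  sig0 <- sig; sig0$coefficients <- list(g1 = 0, g2 = 0); sig0$intercept <- 2
  expect_equal(as.character(score_grouped_linear(ex, sig0)$risk), c("mid", "mid"))

  # all-zero coefficients give the intercept everywhere
  expect_equal(score_grouped_linear(ex, sig0)$score, c(2, 2))
})

test_that("template correlation calls high risk strictly below threshold", {
  tmpl <- c(a = 1, b = -1, c = 0.5, d = 2)
  sig <- list(name = "toy_tmpl", kind = "template_correlation_threshold",
              genes = names(tmpl), template = as.list(tmpl), threshold = 0.4)
  class(sig) <- "signature_definition"
  vals <- cbind(s1 = tmpl, s2 = -tmpl)
  ex <- make_expr(vals, names(tmpl), samples = c("s1", "s2"))
  out <- score_template_correlation(ex, sig)
  expect_equal(out$index, c(1, -1), tolerance = 1e-12)
  expect_equal(out$high_risk, c(FALSE, TRUE))

  # index exactly at the threshold is not high risk
  sig1 <- sig; sig1$threshold <- 1
  out1 <- score_template_correlation(ex, sig1)
  expect_false(out1$high_risk[1])
})

test_that("the full panel scores a synthetic cohort coherently", {
  truth <- generate_metagenes(400, 8, separation = 10, seed = 27)
  ids <- synthetic_gene_ids(truth)
  b <- generate_cohort(truth, 100, noise_sd = 0.1, gene_ids = ids, seed = 28)
  cents <- estimate_centroids(b$expression, b$labels)
  panel <- suppressWarnings(score_panel(b$expression, cents))
  expect_equal(nrow(panel), 100L)
  expect_true(all(is.finite(panel$proliferation)))
  expect_true(all(is.finite(panel$ror)))
  expect_true(all(panel$oncotype_rs >= 0 & panel$oncotype_rs <= 100))
  expect_true(all(abs(panel$mammaprint_index) <= 1))
  # proliferation genes sit in LumB-owned blocks: LumB-dominant cases score
  # higher than LumA-dominant ones on average
  lab <- as.character(b$labels)
  expect_gt(mean(panel$proliferation[lab == "LumB"]),
            mean(panel$proliferation[lab == "LumA"]))
})
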