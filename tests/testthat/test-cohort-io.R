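test_that("expression TSV round-trips byte-identically", {
  dir <- withr::local_tempdir()
  ex <- expr_matrix(matrix(c(1.5, 2, 3, 0.25, 4, 5), nrow = 3,
                           dimnames = list(c("TP53", "EGFR", "ESR1"),
                                           c("s1", "s2"))))
  p1 <- file.path(dir, "a.tsv"); p2 <- file.path(dir, "b.tsv")
  write_expression(ex, p1)
  write_expression(read_expression(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("format errors name the offending gene or cell", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "dup.tsv")
  writeLines(c("gene_id\ts1\ts2", "TP53\t1\t2", "TP53\t3\t4"), p)
  expect_error(read_expression(p), "TP53")
  p2 <- file.path(dir, "bad.tsv")
  writeLines(c("gene_id\ts1", "TP53\t1", "EGFR\tx"), p2)
  expect_error(read_expression(p2), "EGFR")
})

test_that("clinical validation rejects negative times and missing columns", {
  cl <- toy_clinical(10)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cl.tsv")
  cl2 <- cl; cl2$os_months[3] <- -1
  write_clinical(cl2, p)
  expect_error(read_clinical(p), "negative survival time")
  cl3 <- cl; cl3$os_months <- NULL
  write_clinical(cl3, p)
  expect_error(read_clinical(p), "os_months")
})

test_that("merge intersects genes, z-scores within cohort, preserves tags", {
  m1 <- expr_matrix(matrix(rnorm(30, 10), 3, 10,
                           dimnames = list(c("a", "b", "c"), paste0("x", 1:10))),
                    cohort = "c1")
  m2 <- expr_matrix(matrix(rnorm(45, 20, 4), 3, 15,
                           dimnames = list(c("b", "c", "d"), paste0("y", 1:15))),
                    cohort = "c2")
  mg <- merge_cohorts(list(m1, m2), normalization = "zscore")
  expect_equal(mg$expression$gene_ids, c("b", "c"))
  expect_equal(ncol(mg$expression$values), 25L)
  expect_equal(mg$expression$cohort, c(rep("c1", 10), rep("c2", 15)))
  for (co in c("c1", "c2")) {
    v <- mg$expression$values[, mg$expression$cohort == co, drop = FALSE]
    expect_true(all(abs(rowMeans(v)) < 1e-10))
    expect_true(all(abs(apply(v, 1, sd) - 1) < 1e-10))
  }
  # order-insensitive up to column order
  mg2 <- merge_cohorts(list(m2, m1), normalization = "zscore")
  expect_equal(mg2$expression$gene_ids, mg$expression$gene_ids)
  expect_equal(mg2$expression$values[, mg$expression$sample_ids],
               mg$expression$values)
  # no shared genes
  m3 <- expr_matrix(matrix(1:4 + 0.5, 2, 2,
                           dimnames = list(c("zz", "yy"), c("q1", "q2"))))
  expect_error(merge_cohorts(list(m1, m3)), "empty gene intersection")
})

test_that("prepare_nonnegative min-shifts rows and preserves differences", {
  ex <- expr_matrix(matrix(c(-3, 0, 2, 5, 5, 5), nrow = 2, byrow = TRUE,
                           dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
  out <- prepare_nonnegative(ex)
  expect_equal(unname(out$values["g1", ]), c(0, 3, 5))
  expect_equal(unname(out$values["g2", ]), c(0, 0, 0))
  expect_equal(unname(out$shift), c(-3, 5))
  # idempotent on already-shifted input
  out2 <- prepare_nonnegative(out)
  expect_equal(out2$values, out$values)
  # within-row differences preserved exactly
  set.seed(1)
  ex3 <- expr_matrix(matrix(rnorm(50), 5, 10,
                            dimnames = list(paste0("g", 1:5), paste0("s", 1:10))))
  o3 <- prepare_nonnegative(ex3)
  for (g in 1:5)
    expect_equal(diff(o3$values[g, ]), diff(ex3$values[g, ]))
})

test_that("nearest-centroid assignment matches, tie-breaks, and errors", {
  set.seed(21)
  cm <- matrix(rnorm(200), 50, 4,
               dimnames = list(paste0("g", 1:50),
                               c("LumA", "LumB", "HER2", "Basal")))
  cents <- pam50_centroids(cm, "spearman")
  ex <- expr_matrix(cbind(s1 = cm[, "LumA"], s2 = rep(1, 50)),
                    gene_ids = rownames(cm), sample_ids = c("s1", "s2"))
  lab <- assign_pam50(ex, cents)
  expect_equal(as.character(lab$call[["s1"]]), "LumA")
  expect_equal(lab$correlations["LumA", "s1"], 1)
  # constant sample: all correlations undefined -> first subtype by order
  expect_equal(as.character(lab$call[["s2"]]), "LumA")
  # spearman calls are invariant to strictly monotone per-sample transforms
  ex_t <- ex; ex_t$values[, 1] <- exp(ex$values[, 1] / 2)
  expect_equal(as.character(assign_pam50(ex_t, cents)$call[["s1"]]), "LumA")
  # coverage error below 25 shared genes
  ex_small <- expr_matrix(ex$values[1:10, , drop = FALSE])
  expect_error(assign_pam50(ex_small, cents), "coverage")
})

test_that("classifier recovers generated labels on separated synthetic data", {
  b <- reference_cohort(n = 200, m = 300, k_true = 8, separation = 10,
                        noise_sd = 0.1, seed = 13)
  cents <- estimate_centroids(b$expression, b$labels)
  lab <- assign_pam50(b$expression, cents, min_genes = 25)
  agreement <- mean(as.character(lab$call) == as.character(b$labels))
  expect_gte(agreement, 0.95)
})

test_that("subtype filter removes Normal everywhere, Claudin-low per cohort", {
  vals <- matrix(runif(40, 1, 2), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  ex <- expr_matrix(vals, cohort = c(rep("metabric", 5), rep("tcga", 5)))
  labels <- factor(c("LumA", "Normal", "ClaudinLow", "LumB", "Basal",
                     "LumA", "Normal", "ClaudinLow", "HER2", "LumA"),
                   levels = c("LumA", "LumB", "HER2", "Basal", "Normal",
                              "ClaudinLow"))
  bundle <- structure(list(expression = ex, labels = labels, onehot = NULL,
                           clinical = NULL, cohort_id = "merged", truth = NULL),
                      class = "cohort_bundle")
  suppressMessages(out <- filter_subtypes(bundle))
  kept <- as.character(out$labels)
  # both Normals removed; Claudin-low removed only from the metabric cohort
  expect_equal(sum(kept == "Normal"), 0L)
  expect_equal(out$expression$sample_ids,
               c("s1", "s4", "s5", "s6", "s8", "s9", "s10"))
  expect_true("ClaudinLow" %in% kept)   # the TCGA-flagged one survives
  all4 <- structure(list(expression = ex,
                         labels = factor(rep("Normal", 10),
                                         levels = levels(labels)),
                         onehot = NULL, clinical = NULL,
                         cohort_id = "merged", truth = NULL),
                    class = "cohort_bundle")
  expect_error(suppressMessages(filter_subtypes(all4)), "empty cohort")
})
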