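# Shared fixtures built in code at test time.

# A tiny labeled instance with an exact factorization: B0 = I (k = 4),
# S0 = L, X = A0 L, so the ssNMF optimum is exactly zero.
exact_factorization_instance <- function(m = 50L, n = 40L, seed = 11L) {
  set.seed(seed)
  labels <- factor(sample(c("LumA", "LumB", "HER2", "Basal"), n, replace = TRUE),
                   levels = c("LumA", "LumB", "HER2", "Basal"))
  L <- onehot_matrix(labels)
  A0 <- matrix(runif(m * 4L, 0.1, 2), m, 4L)
  list(X = A0 %*% L, L = L, A0 = A0, labels = labels)
}

# Reference synthetic cohort used by the recovery checks.
reference_cohort <- function(n = 200L, m = 500L, k_true = 8L,
                             separation = 10, noise_sd = 0.1, seed = 7L) {
  truth <- generate_metagenes(m, k_true, separation = separation, seed = seed)
  generate_cohort(truth, n, noise_sd = noise_sd, cohort_id = "ref",
                  seed = seed + 1L)
}

# Small clinical table helper for association tests.
toy_clinical <- function(n, seed = 5L) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             age = rnorm(n, 60, 8),
             node_positive = rbinom(n, 1, 0.4),
             size_gt20 = rbinom(n, 1, 0.5),
             stage_gt1 = rbinom(n, 1, 0.6),
             er_pos = rbinom(n, 1, 0.95),
             pr_pos = rbinom(n, 1, 0.8),
             her2_pos = rbinom(n, 1, 0.08),
             tnbc = 0L,
             mut_TP53 = rbinom(n, 1, 0.1),
             mut_PIK3CA = rbinom(n, 1, 0.45),
             mut_CBFB = rbinom(n, 1, 0.06),
             os_months = rexp(n, log(2) / 150),
             os_event = rbinom(n, 1, 0.5),
             stringsAsFactors = FALSE)
}

# Independent two-sided Fisher p-value by hypergeometric enumeration:
# sum the probabilities of all tables (fixed margins) no more likely than
# the observed one.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
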